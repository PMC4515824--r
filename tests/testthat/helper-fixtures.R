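# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

healthy_donor <- function() {
  fixture("healthy_donor", function() build_healthy_profile(seed = 101L))
}

healthy_capture <- function() {
  fixture("healthy_capture", function() {
    simulate_capture(healthy_donor(), seed = 101L)
  })
}

# a rendered mixed field exercising every classifiable morphotype
mixed_field <- function() {
  fixture("mixed_field", function() {
    morphs <- c(rep("small", 70), rep("large", 14), rep("granular", 26),
                rep("lobed", 8), rep("granular_lobed", 8),
                rep("monocyte", 50), rep("reactive", 5), rep("binuclear", 3))
    set.seed(202L)
    ros <- simple_roster(length(morphs), morphs)
    ros$diameter_um <- sample_diameters(ros$morphotype)
    img <- render_spot(ros, list(type = "rect", w = 320, h = 320),
                       render_params(pixel_scale = 0.15), seed = 202L)
    seg <- segment_cells(img)
    mt <- morphometry_table(img, seg)
    list(img = img, seg = seg, measured = mt,
         matched = match_ground_truth(mt, img$ground_truth))
  })
}

# brute-force Mann-Whitney oracle: enumerate group assignments by bitmask
mw_oracle_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- c()
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    if (sum(bits) != n1) next
    us <- c(us, sum(rk[bits == 1L]) - n1 * (n1 + 1) / 2)
  }
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
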