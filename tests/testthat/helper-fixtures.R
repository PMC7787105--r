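# Shared fixtures, memoized so that the expensive synthetic pipelines are
# built once per test run and reused across files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# minimal C5 ring crystal: fast enough for unit tests
tiny_case <- function() memo("tiny",
  do.call(make_ring_case, c(ring_preset("tiny-c5"), list(seed = 3))))

# small EM-style map of the tiny ring (the preset skips it)
tiny_em <- function() memo("tiny_em",
  simulate_em_map(tiny_case()$em_model, resolution = 6, pixel_size = 1.37,
                  pad = 10))

# memoized SRF analysis of the tiny case
tiny_srf <- function() memo("tiny_srf", {
  eng <- srf_engine(tiny_case()$refl_obs)
  det <- detect_ncs_order(eng, candidates = 4:6)
  list(eng = eng, det = det)
})

# the C13 "portal-mini" study case and its analysis products
mini_case <- function() memo("mini13", make_ring_case(seed = 7))

mini_case12 <- function() memo("mini12",
  do.call(make_ring_case, c(ring_preset("portal-mini-c12"),
                            list(seed = 11, em_map = FALSE))))

mini_srf <- function() memo("srf13", {
  eng <- srf_engine(mini_case()$refl_obs)
  det <- detect_ncs_order(eng, candidates = 11:14)
  list(eng = eng, det = det)
})

mini_srf12 <- function() memo("srf12", {
  eng <- srf_engine(mini_case12()$refl_obs)
  det <- detect_ncs_order(eng, candidates = 11:14)
  list(eng = eng, det = det)
})

# placed 36% polyalanine partial ring on the C13 case
mini_placement <- function() memo("place13", {
  case <- mini_case()
  det <- mini_srf()$det
  ring <- expand_cn(case$partial_monomer,
                    cn_operators(case$params$n, c(0, 0, 1), c(0, 0, 0)))
  pl <- search_placement(ring, case$refl_obs, theta = det$peak$theta,
                         phi = det$peak$phi, order = case$params$n)
  list(ring = ring, pl = pl, placed = apply_placement(ring, pl))
})

# starting phase set from the placed partial model (to 7.9 A)
mini_start <- function() memo("start13", {
  case <- mini_case()
  fc <- calc_structure_factors(mini_placement()$placed, case$cell, case$sg,
                               d_min = min(case$refl_obs$d))
  start <- phase_recombine(case$refl_obs, fc)
  start$phi[start$d < 7.9] <- NA_real_
  start$fom[start$d < 7.9] <- NA_real_
  start
})

# full default-protocol DM run on the mini case
mini_dm <- function() memo("dm13", {
  case <- mini_case()
  pl <- mini_placement()$pl
  ops <- cn_operators(case$params$n, attr(pl, "axis"),
                      placement_ring_center(pl))
  run_dm(mini_start(), dm_config(solvent_fraction = 0.9), ops = ops,
         em_map = case$em_map, placement = pl, hist_ref = case$refl_truth)
})

# 50-atom toy model in a small P212121 cell (structure-factor oracle tests)
toy_model <- function() memo("toy", {
  set.seed(42)
  n <- 50
  atomic_model(data.frame(
    serial = 1:n,
    name = sample(c("N", "CA", "C", "O", "CB"), n, replace = TRUE),
    res_name = "ALA", chain = "A", res_seq = 1:n,
    x = runif(n, 2, 16), y = runif(n, 2, 18), z = runif(n, 2, 20),
    occ = 1, b = runif(n, 15, 30),
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE,
                     prob = c(0.6, 0.2, 0.15, 0.05))))
})

toy_cell <- function() unit_cell(20, 22, 24)

# angle between two axis directions, sign-insensitive, in degrees
axis_angle <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}
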