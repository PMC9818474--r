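# Fixture builders and independent brute-force oracles. The oracles work
# straight from the raw temperature vectors with explicit loops, never
# through the package's scoring path.

make_constant_tg <- function(skin = 31.0, int = 34.0, id = "const") {
  thermogram(id, rep(skin, 10), rep(skin, 10), rep(int, 10), rep(int, 10),
             t_skin_ref = rep(skin, 2), t_int_ref = rep(int, 2))
}

make_random_tg <- function(seed, id = paste0("rnd-", seed)) {
  set.seed(seed)
  thermogram(id,
             t_skin_right = runif(10, 29, 34),
             t_skin_left = runif(10, 29, 34),
             t_int_right = runif(10, 32, 37),
             t_int_left = runif(10, 32, 37),
             t_skin_ref = runif(2, 29, 34),
             t_int_ref = runif(2, 32, 37))
}

# Sums max-minus-mean per channel pool by explicit iteration.
oracle_qmax <- function(tg) {
  pool_mw <- c(tg$t_int_right, tg$t_int_left)
  pool_ir <- c(tg$t_skin_right, tg$t_skin_left)
  mx_mw <- -Inf; s_mw <- 0
  for (v in pool_mw) { if (v > mx_mw) mx_mw <- v; s_mw <- s_mw + v }
  mx_ir <- -Inf; s_ir <- 0
  for (v in pool_ir) { if (v > mx_ir) mx_ir <- v; s_ir <- s_ir + v }
  max(mx_mw - s_mw / 20, mx_ir - s_ir / 20)
}

oracle_asymmetry <- function(tg) {
  k_int <- -Inf; n_int <- NA; k_skin <- -Inf; n_skin <- NA
  for (i in 1:10) {
    d <- abs(tg$t_int_left[[i]] - tg$t_int_right[[i]])
    if (d > k_int) { k_int <- d; n_int <- i - 1L }
    d <- abs(tg$t_skin_left[[i]] - tg$t_skin_right[[i]])
    if (d > k_skin) { k_skin <- d; n_skin <- i - 1L }
  }
  list(k_int = k_int, n_int = n_int, k_skin = k_skin, n_skin = n_skin)
}

# Evaluates the same-point and cross-channel constructions directly.
oracle_r <- function(tg) {
  a <- oracle_asymmetry(tg)
  if (a$n_int == a$n_skin) return(a$k_int + a$k_skin)
  if (a$k_int >= a$k_skin) {
    i <- a$n_int + 1L
    a$k_int + abs(tg$t_skin_left[[i]] - tg$t_skin_right[[i]])
  } else {
    i <- a$n_skin + 1L
    a$k_skin + abs(tg$t_int_left[[i]] - tg$t_int_right[[i]])
  }
}

patientP_panel <- function(which = c("initial_labels", "followup_labels",
                                     "initial_concentrations")) {
  which <- match.arg(which)
  read_panel_csv(system.file("extdata",
                             paste0("patientP_", which, ".csv"),
                             package = "mwrisk"))
}
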