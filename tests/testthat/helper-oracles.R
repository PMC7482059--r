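# Independent oracles used across the suite.

# brute-force exact two-sided signed-rank p-value: enumerate all 2^n sign
# assignments of the informative differences (midranks under ties)
brute_signed_rank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s]))
  p_low <- mean(Ws <= W + 1e-12)
  p_high <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(p_low, p_high))
}

# check a full reaction vector against a polytope's constraints directly
# (membership without any LP): balances, pins, and lower bounds
satisfies_polytope <- function(poly, s, tol = 1e-8) {
  ok_eq <- max(abs(poly$Aeq %*% s - poly$beq)) <= tol
  fin <- is.finite(poly$lb)
  ok_lb <- all(s[fin] >= poly$lb[fin] - tol)
  ok_eq && ok_lb
}

# the full shipped configuration grid used by the conservation and
# LP-vs-vertex acceptance checks
shipped_configurations <- function() {
  configs <- list()
  relaxable <- c("acetate", "propionate", "butyrate", "H2", "CH4", "CO2")
  for (fiber in c("inulin", "pectin")) {
    for (conv in c("anhydro", "monosaccharide")) {
      for (wm in c("free", "nonnegative")) {
        base <- fiber_polytope(fiber, conv, water_mode = wm)
        key <- paste(fiber, conv, wm, sep = ".")
        configs[[paste0(key, ".closed")]] <- base
        configs[[paste0(key, ".biomass15")]] <- apply_biomass_yield(base, 0.15)
        for (pr in relaxable) {
          if (max_product(base, pr) <= 1e-9) next
          configs[[paste0(key, ".relax_", pr)]] <- relax_input(base, pr, 1 / 3)
        }
      }
    }
  }
  configs
}
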