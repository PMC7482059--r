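## Seeded synthetic communities, ground-truth reaction vectors inside the
## product polytope, and noisy treatment/control measurements. The generator
## emulates the design of the ex vivo experiment: 9 subjects x
## {control, inulin, pectin} x 3 replicates, controls producing about one
## third as much as treatments, a planted hydrogen-producer taxon whose
## abundance scales H2 yield, and ~20% methanogen-positive subjects who alone
## produce CH4.

#' Generate synthetic gut communities
#'
#' Log-normal taxon abundances normalized to relative abundance per subject,
#' one designated hydrogen-producer taxon, and Bernoulli methanogen carrier
#' flags.
#'
#' @param n_subjects Number of subjects (default 9, the experiment's size).
#' @param n_taxa Number of taxa (>= 2).
#' @param methanogen_prevalence Probability a subject carries methanogens
#'   (default 0.2, the HMP survey figure).
#' @param sdlog Log-scale standard deviation of the bulk abundance
#'   distribution (default 2, a heavy-tailed profile typical of 16S surveys).
#' @param producer_meanlog,producer_sdlog Log-normal parameters of the planted
#'   hydrogen producer's raw weight before normalization. The defaults
#'   (log(30), 0.6) make it a common taxon — median relative abundance around
#'   8%, spanning roughly 2–25% across subjects — matching the regime in which
#'   a single abundant taxon visibly drives the hydrogen yield.
#' @param seed RNG seed; same seed, same table.
#' @return List with `abundance` (subjects x taxa, rows sum to 1), `producer`
#'   (planted taxon index), `methanogen` (logical per subject), `seed`.
#' @export
generate_communities <- function(n_subjects = 9, n_taxa = 50,
                                 methanogen_prevalence = 0.2, sdlog = 2,
                                 producer_meanlog = log(30),
                                 producer_sdlog = 0.6,
                                 seed = 1) {
  if (n_taxa < 2L || n_subjects < 1L) stop("degenerate community size")
  if (methanogen_prevalence < 0 || methanogen_prevalence > 1) {
    stop("prevalence must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  ab <- matrix(stats::rlnorm(n_subjects * n_taxa, meanlog = 0, sdlog = sdlog),
               n_subjects, n_taxa)
  producer <- sample.int(n_taxa, 1L)
  ab[, producer] <- stats::rlnorm(n_subjects, producer_meanlog, producer_sdlog)
  ab <- ab / rowSums(ab)
  dimnames(ab) <- list(paste0("S", seq_len(n_subjects)),
                       paste0("taxon_", seq_len(n_taxa)))
  methanogen <- stats::runif(n_subjects) < methanogen_prevalence
  names(methanogen) <- rownames(ab)
  list(abundance = ab, producer = producer, methanogen = methanogen,
       seed = seed)
}

#' Ground-truth reaction vectors inside a product polytope
#'
#' Each subject's fermentation outcome is a convex combination of the
#' polytope's vertices with Dirichlet(1) weights, exponentially tilted toward
#' high-H2 vertices in proportion to the subject's planted-producer abundance:
#' weight_k proportional to g_k * exp(effect_strength * abundance * H2_k
#' + sum(product_tilt * vertex_k)), g_k ~ Exp(1). Convexity guarantees every
#' sampled vector satisfies all balances and bounds exactly.
#'
#' @param poly A `product_polytope` (vertices are enumerated on demand).
#' @param community Output of [generate_communities()], or a numeric vector of
#'   producer abundances per subject.
#' @param effect_strength Strength of the producer-abundance tilt on H2-rich
#'   vertices (default 1.5 per mol H2 per unit relative abundance, chosen so
#'   that across the default producer abundance range the expected hydrogen
#'   yield moves near-linearly over most of its feasible span, the regime of
#'   the strong abundance-H2 association seen experimentally).
#' @param product_tilt Optional named vector of per-product linear tilts
#'   applied to all subjects (fiber-specific preferences, e.g.
#'   `c(acetate = 1.5)` for pectin).
#' @param stochastic If `TRUE` (default) weights are a Dirichlet(1) draw times
#'   the exponential tilt; if `FALSE` the deterministic tilted-mixture mean
#'   (softmax weights) is returned — the generator's noiseless limit.
#' @param exclude_products Products forced to exactly zero by dropping every
#'   vertex where they are positive (default `"CH4"`: a purely fermentative
#'   community makes no methane; methanogenesis is layered on separately for
#'   carrier subjects via [apply_methanogenesis()]).
#' @param seed RNG seed (ignored when `stochastic = FALSE`).
#' @return Matrix subjects x species of feasible reaction vectors.
#' @export
sample_reaction_vectors <- function(poly, community, effect_strength = 1.5,
                                    product_tilt = NULL, stochastic = TRUE,
                                    exclude_products = "CH4", seed = 1) {
  V <- enumerate_vertices(poly)
  for (p in intersect(exclude_products, colnames(V))) {
    V <- V[V[, p] <= poly$config$tol_eq, , drop = FALSE]
    V[, p] <- 0 # clear sub-tolerance dust so excluded products are exact zeros
  }
  if (nrow(V) == 0L) stop("polytope has no vertices")
  ab <- if (is.list(community)) community$abundance[, community$producer] else community
  if (stochastic && !is.null(seed)) set.seed(seed)
  nm <- colnames(V)
  tilt_lin <- rep(0, nrow(V))
  if (!is.null(product_tilt)) {
    bad <- setdiff(names(product_tilt), nm)
    if (length(bad)) stop("unknown product in tilt: ", paste(bad, collapse = ", "))
    tilt_lin <- as.numeric(V[, names(product_tilt), drop = FALSE] %*% product_tilt)
  }
  h2 <- if ("H2" %in% nm) V[, "H2"] else rep(0, nrow(V))
  out <- t(vapply(ab, function(a) {
    g <- if (stochastic) stats::rexp(nrow(V)) else rep(1, nrow(V))
    w <- g * exp(effect_strength * a * h2 + tilt_lin)
    w <- w / sum(w)
    as.numeric(crossprod(V, w))
  }, numeric(ncol(V))))
  colnames(out) <- nm
  rownames(out) <- if (is.list(community)) rownames(community$abundance) else names(ab)
  out
}

#' Apply hydrogenotrophic methanogenesis to a reaction vector
#'
#' Converts a fraction of the net H2 by 4 H2 + CO2 -> CH4 + 2 H2O, capped by
#' the available CO2. The conversion reaction is itself balanced, so the
#' output satisfies every balance the input did. Intended for
#' methanogen-positive subjects only.
#'
#' @param vector Named reaction vector (must contain H2, CO2, CH4, H2O).
#' @param conversion_fraction Fraction phi of net H2 converted, in [0, 1].
#' @return The adjusted reaction vector.
#' @examples
#' v <- c(H2 = 8, CO2 = 4, CH4 = 0, H2O = 0)
#' apply_methanogenesis(v, 0.5) # H2 4, CO2 3, CH4 1, H2O 2
#' @export
apply_methanogenesis <- function(vector, conversion_fraction) {
  if (conversion_fraction < 0 || conversion_fraction > 1) {
    stop("conversion_fraction must be in [0, 1]")
  }
  need <- c("H2", "CO2", "CH4", "H2O")
  if (!all(need %in% names(vector))) stop("vector must contain H2, CO2, CH4, H2O")
  extent <- min(conversion_fraction * max(vector[["H2"]], 0) / 4, vector[["CO2"]])
  vector[["H2"]] <- vector[["H2"]] - 4 * extent
  vector[["CO2"]] <- vector[["CO2"]] - extent
  vector[["CH4"]] <- vector[["CH4"]] + extent
  vector[["H2O"]] <- vector[["H2O"]] + 2 * extent
  vector
}

#' Noisy treatment and control measurements from ground-truth vectors
#'
#' Emits a replicate-level measurement table. Treatment amounts are
#' (truth + control_fraction * baseline) * fiber_mol per product; control
#' amounts are control_fraction * baseline * reference_mol — the baseline is
#' the subject's residue fermentation, present identically under treatment
#' and control, so treatment-minus-control accounting recovers the truth
#' exactly at zero noise. Each replicate is perturbed by multiplicative
#' lognormal noise exp(N(0, noise_sd)), which keeps amounts positive.
#'
#' @param truth List of per-fiber truth matrices (subjects x species, mol per
#'   mol fiber), names = fiber names.
#' @param fiber_mols Named vector of moles of fiber monomer per fiber.
#' @param baseline Subjects x products matrix of the residue-fermentation
#'   interior point (mol per mol reference substrate).
#' @param control_fraction Scale of the control output relative to a fiber
#'   batch (default 1/3, the observed control/treatment ratio).
#' @param noise_sd Lognormal sigma (default 0.05, from the stated ~5% assay
#'   accuracy).
#' @param n_replicates Replicates per condition (default 3).
#' @param seed RNG seed.
#' @return Data frame: `subject`, `fiber` (including control rows),
#'   `replicate`, and `*_mol` product columns.
#' @export
generate_measurements <- function(truth, fiber_mols, baseline,
                                  control_fraction = 1 / 3, noise_sd = 0.05,
                                  n_replicates = 3, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  prods <- names(.PRODUCT_COLS)
  subjects <- rownames(truth[[1]])
  ref_mol <- mean(fiber_mols)
  rows <- list()
  noise <- function(k) exp(stats::rnorm(k, 0, noise_sd))
  for (si in seq_along(subjects)) {
    base_amt <- control_fraction * baseline[si, prods] * ref_mol
    for (r in seq_len(n_replicates)) {
      amt <- base_amt * noise(length(prods))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[si], fiber = "control", replicate = r,
        t(stats::setNames(amt, .PRODUCT_COLS[prods])), check.names = FALSE)
    }
    for (fb in names(truth)) {
      tr <- truth[[fb]][si, prods] * fiber_mols[[fb]] + base_amt
      for (r in seq_len(n_replicates)) {
        amt <- tr * noise(length(prods))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjects[si], fiber = fb, replicate = r,
          t(stats::setNames(amt, .PRODUCT_COLS[prods])), check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the full ex vivo experiment
#'
#' End-to-end seeded simulation: communities, per-fiber ground-truth reaction
#' vectors (with fiber-specific product tilts: inulin toward the reduced
#' products butyrate and H2, pectin toward acetate), methanogenesis applied in
#' methanogen-positive subjects only, a per-subject residue baseline, and a
#' replicate-level measurement table at the experimental doses (10 g/L inulin,
#' 5 g/L pectin, 2 mL slurry).
#'
#' @inheritParams generate_communities
#' @inheritParams sample_reaction_vectors
#' @param fibers Fibers to simulate (default inulin and pectin).
#' @param conversion_fraction H2-to-CH4 conversion in methanogen carriers
#'   (default 0.5).
#' @param control_fraction,noise_sd,n_replicates See [generate_measurements()].
#' @param convention Monomer convention for polytopes and doses.
#' @param seed Master seed; all stage seeds derive from it.
#' @return List with `community`, `polytopes`, `truth` (per fiber), `baseline`,
#'   `measurements`, `fiber_mols`, `seed`.
#' @export
simulate_experiment <- function(n_subjects = 9, fibers = c("inulin", "pectin"),
                                n_taxa = 50, methanogen_prevalence = 0.2,
                                effect_strength = 1.5,
                                conversion_fraction = 0.5,
                                control_fraction = 1 / 3, noise_sd = 0.05,
                                n_replicates = 3,
                                convention = "anhydro", seed = 1) {
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4 + length(fibers))
  community <- generate_communities(n_subjects, n_taxa, methanogen_prevalence,
                                    seed = stage_seeds[1])
  polys <- lapply(fibers, function(fb) fiber_polytope(fb, convention))
  names(polys) <- fibers
  ## fiber-specific preferences: inulin (more reduced) toward butyrate with the
  ## full producer-driven H2 effect; pectin (more oxidized) toward acetate with
  ## a much weaker H2 effect, as pectin H2 production is low across subjects
  tilts <- list(inulin = c(butyrate = 2), pectin = c(acetate = 2))
  effect_by_fiber <- c(inulin = 1, pectin = 0.3)
  truth <- list()
  for (k in seq_along(fibers)) {
    fb <- fibers[k]
    mult <- if (fb %in% names(effect_by_fiber)) effect_by_fiber[[fb]] else 1
    tv <- sample_reaction_vectors(polys[[fb]], community,
                                  effect_strength * mult,
                                  product_tilt = tilts[[fb]],
                                  seed = stage_seeds[2 + k])
    for (si in which(community$methanogen)) {
      tv[si, ] <- apply_methanogenesis(tv[si, ], conversion_fraction)
    }
    truth[[fb]] <- tv
  }
  baseline <- sample_reaction_vectors(polys[[1]], rep(0, n_subjects),
                                      effect_strength = 0,
                                      seed = stage_seeds[2])
  rownames(baseline) <- rownames(community$abundance)
  doses <- c(inulin = 10, pectin = 5)[fibers]
  fiber_mols <- vapply(fibers, function(fb) {
    fiber_moles(doses[[fb]], 0.002, fb, convention)
  }, 0)
  measurements <- generate_measurements(truth, fiber_mols, baseline,
                                        control_fraction, noise_sd,
                                        n_replicates,
                                        seed = stage_seeds[2 + length(fibers) + 1])
  list(community = community, polytopes = polys, truth = truth,
       baseline = baseline, measurements = measurements,
       fiber_mols = fiber_mols, seed = seed)
}

#' Write a simulated experiment to plain-text files
#'
#' Emits `measurements.csv` and `asv_table.tsv` (samples x taxa relative
#' abundances) into a directory.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  ab <- data.frame(sample = rownames(sim$community$abundance),
                   sim$community$abundance, check.names = FALSE)
  utils::write.table(ab, file.path(dir, "asv_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
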