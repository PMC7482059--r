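## Ex vivo product accounting: raw headspace/slurry measurements to net
## mol-product-per-mol-fiber profiles, and comparison against polytopes.

.GAS_CONSTANT_L_ATM <- 0.0820573660809596 # L atm / (mol K)

.PRODUCT_COLS <- c(acetate = "acetate_mol", propionate = "propionate_mol",
                   butyrate = "butyrate_mol", H2 = "h2_mol", CH4 = "ch4_mol",
                   CO2 = "co2_mol")

#' Moles of a gas in the bottle headspace
#'
#' Ideal-gas conversion of a chromatographic mole fraction:
#' n = x * P * V / (R * T).
#'
#' @param mole_fraction Gas mole fraction in the headspace, in [0, 1].
#' @param headspace_volume Headspace volume in litres.
#' @param temperature Temperature in kelvin (37 C incubation = 310.15 K).
#' @param pressure Total headspace pressure in atm (default 1, assumed at
#'   sampling unless measured).
#' @return Moles of gas.
#' @examples
#' headspace_moles(0.10, 0.058, 310.15) # 2.279e-4
#' @export
headspace_moles <- function(mole_fraction, headspace_volume, temperature,
                            pressure = 1) {
  if (any(mole_fraction < 0 | mole_fraction > 1)) stop("mole_fraction must be in [0, 1]")
  if (any(headspace_volume <= 0) || any(temperature <= 0) || any(pressure <= 0)) {
    stop("volume, temperature and pressure must be positive")
  }
  mole_fraction * pressure * headspace_volume / (.GAS_CONSTANT_L_ATM * temperature)
}

#' Moles of fiber monomer in a slurry sample
#'
#' @param dose_g_per_L Fiber dose in g/L (the experiment used 10 g/L inulin
#'   and 5 g/L pectin).
#' @param slurry_volume Slurry volume in litres (2 mL = 0.002).
#' @param fiber `"inulin"` or `"pectin"`.
#' @param convention Monomer molar-mass convention; `"anhydro"` (default,
#'   162.14 / 176.12 g/mol) or `"monosaccharide"` (180.16 / 194.14 g/mol).
#' @return Moles of monomer.
#' @examples
#' fiber_moles(10, 0.002, "inulin") # 1.234e-4
#' @export
fiber_moles <- function(dose_g_per_L, slurry_volume,
                        fiber = c("inulin", "pectin"),
                        convention = c("anhydro", "monosaccharide")) {
  if (any(dose_g_per_L <= 0)) stop("dose must be positive")
  if (any(slurry_volume <= 0)) stop("slurry volume must be positive")
  mm <- molar_mass(monomer_species(match.arg(fiber), match.arg(convention)))
  dose_g_per_L * slurry_volume / mm
}

#' Net production profile: treatment minus control, per mole of fiber
#'
#' The slurry ferments residual material even without added fiber, so the
#' products attributable to the fiber are the difference between the mean of
#' the treatment replicates and the mean of the subject's no-fiber controls,
#' divided by the moles of fiber added. Negative net values are meaningful
#' (net uptake from the residue subsystem) and are preserved.
#'
#' @param treatment Data frame of treatment replicates: columns `subject`,
#'   `fiber`, `replicate` and the product amount columns `acetate_mol`,
#'   `propionate_mol`, `butyrate_mol`, `h2_mol`, `ch4_mol`, `co2_mol`.
#' @param control Data frame of the same subject's control replicates (same
#'   columns, fiber `"control"`).
#' @param fiber_mol Moles of fiber monomer added (see [fiber_moles()]).
#' @param aggregate `"mean"` (default) or `"median"` replicate aggregation.
#' @return A `net_product_profile`: list with `subject`, `fiber`, `products`
#'   (named mol/mol vector), `replicate_sd` (propagated as
#'   sqrt(var_t/n_t + var_c/n_c)/fiber_mol; `NA` when either side has a single
#'   replicate), and replicate counts.
#' @export
net_production <- function(treatment, control, fiber_mol,
                           aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!nrow(treatment) || !nrow(control)) stop("empty replicate set")
  if (length(unique(treatment$subject)) != 1L || length(unique(control$subject)) != 1L) {
    stop("replicates must come from a single subject")
  }
  if (unique(treatment$subject) != unique(control$subject)) {
    stop("subject mismatch between treatment and control")
  }
  if (fiber_mol <= 0) stop("fiber_mol must be positive")
  cols <- .PRODUCT_COLS[.PRODUCT_COLS %in% names(treatment) & .PRODUCT_COLS %in% names(control)]
  if (!length(cols)) stop("no product amount columns found")
  agg <- if (aggregate == "mean") mean else stats::median
  tmean <- vapply(cols, function(cl) agg(treatment[[cl]]), 0)
  cmean <- vapply(cols, function(cl) agg(control[[cl]]), 0)
  nt <- nrow(treatment)
  nc <- nrow(control)
  sds <- vapply(cols, function(cl) {
    if (nt < 2L || nc < 2L) return(NA_real_)
    sqrt(stats::var(treatment[[cl]]) / nt + stats::var(control[[cl]]) / nc) / fiber_mol
  }, 0)
  products <- (tmean - cmean) / fiber_mol
  names(products) <- names(cols)
  names(sds) <- names(cols)
  structure(list(subject = unique(treatment$subject),
                 fiber = unique(treatment$fiber),
                 products = products, replicate_sd = sds,
                 n_treatment = nt, n_control = nc, fiber_mol = fiber_mol),
            class = "net_product_profile")
}

#' @export
print.net_product_profile <- function(x, ...) {
  cat(sprintf("<net_product_profile> subject %s, fiber %s (%d treatment / %d control replicates)\n",
              x$subject, x$fiber, x$n_treatment, x$n_control))
  print(round(x$products, 4))
  invisible(x)
}

#' Net profiles for every subject x fiber in a measurement table
#'
#' @param measurements Data frame in the layout of [generate_measurements()]
#'   or `measurements.csv`: `subject`, `fiber` (including `"control"` rows),
#'   `replicate`, product amount columns. Cellulose rows are dropped by
#'   default (insoluble; indistinguishable from control in the experiment).
#' @param fiber_mols Named vector of moles of monomer per fiber, e.g.
#'   `c(inulin = 1.234e-4, pectin = 5.678e-5)`.
#' @param drop_fibers Fibers excluded from modeling (default `"cellulose"`).
#' @param ... Passed to [net_production()].
#' @return List of `net_product_profile` objects, plus a `profile_matrix()`
#'   friendly data frame via [profiles_to_matrix()].
#' @export
net_production_all <- function(measurements, fiber_mols,
                               drop_fibers = "cellulose", ...) {
  fibers <- setdiff(unique(measurements$fiber), c("control", drop_fibers))
  out <- list()
  for (subj in unique(measurements$subject)) {
    ctrl <- measurements[measurements$subject == subj & measurements$fiber == "control", , drop = FALSE]
    for (fb in fibers) {
      trt <- measurements[measurements$subject == subj & measurements$fiber == fb, , drop = FALSE]
      if (!nrow(trt) || !nrow(ctrl)) next
      if (!fb %in% names(fiber_mols)) stop("no fiber_mols entry for ", fb)
      out[[paste(subj, fb, sep = ".")]] <- net_production(trt, ctrl, fiber_mols[[fb]], ...)
    }
  }
  out
}

#' Stack net profiles into a samples x products matrix
#'
#' @param profiles List of `net_product_profile` (from [net_production_all()]).
#' @return Numeric matrix with rownames `subject.fiber`, plus attributes
#'   `subject` and `fiber`.
#' @export
profiles_to_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0)
  prods <- names(profiles[[1]]$products)
  m <- t(vapply(profiles, function(p) p$products[prods], numeric(length(prods))))
  colnames(m) <- prods
  rownames(m) <- names(profiles)
  attr(m, "subject") <- vapply(profiles, function(p) as.character(p$subject), "")
  attr(m, "fiber") <- vapply(profiles, function(p) as.character(p$fiber), "")
  m
}

#' Compare a measured net profile against a product polytope
#'
#' Delegates to [check_feasibility()] and additionally reports, for each
#' requested 2D projection, whether the measured point lies inside the hull
#' (within tolerance).
#'
#' @param profile A `net_product_profile` or a named mol/mol vector.
#' @param poly A `product_polytope`.
#' @param tolerance Measurement band half-width for the feasibility LP.
#' @param projections Optional list of 2-element character vectors naming
#'   product pairs to test against the 2D hulls.
#' @return List with the `feasibility_report` and, per projection, a logical
#'   `inside` flag.
#' @export
profile_vs_polytope <- function(profile, poly, tolerance = 1e-8,
                                projections = NULL) {
  measured <- if (inherits(profile, "net_product_profile")) profile$products else profile
  measured <- measured[names(measured) %in% names(poly$lb)]
  rep <- check_feasibility(poly, measured, tolerance)
  proj_res <- list()
  if (!is.null(projections)) {
    for (pr in projections) {
      hull <- project_2d(poly, pr[1], pr[2])
      pt <- c(measured[pr[1]], measured[pr[2]])
      proj_res[[paste(pr, collapse = ":")]] <- .point_in_hull(pt, hull$hull, tolerance)
    }
  }
  list(report = rep, projections = proj_res)
}

## point-in-convex-polygon with tolerance; handles degenerate hulls
.point_in_hull <- function(pt, hull, tol = 1e-8) {
  if (nrow(hull) == 0L) return(FALSE)
  if (nrow(hull) == 1L) return(max(abs(pt - hull[1, ])) <= tol)
  if (nrow(hull) == 2L) {
    a <- hull[1, ]; b <- hull[2, ]
    ab <- b - a
    t <- sum((pt - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    return(sqrt(sum((a + t * ab - pt)^2)) <= tol)
  }
  n <- nrow(hull)
  sgn <- vapply(seq_len(n), function(i) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
  }, 0)
  all(sgn >= -tol) || all(sgn <= tol)
}

#' Exact paired difference test (Wilcoxon signed rank)
#'
#' Exact two-sided signed-rank test for paired per-subject values under two
#' fibers. Zero differences are dropped (count reported); ties in the absolute
#' differences get midranks. The null distribution is computed by exact
#' enumeration of all 2^n sign assignments (via generating-function
#' convolution), so n = 9 with all differences concordant gives
#' p = 2/512 = 0.00390625. A sign-flip permutation test on the mean difference
#' is available as an alternative.
#'
#' @param x,y Paired numeric vectors (same subjects, same order).
#' @param method `"signed_rank"` (default, exact) or `"permutation_t"`
#'   (exact sign-flip permutation of the mean difference).
#' @return List with `statistic` (W, sum of positive-difference ranks),
#'   `p_value`, `n_used`, `n_zero_dropped`, `method`.
#' @examples
#' paired_difference_test(2:10, 1:9)$p_value # 2/512
#' @export
paired_difference_test <- function(x, y, method = c("signed_rank", "permutation_t")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length (paired)")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    ## identical vectors: nothing to test, not an error
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                n_zero_dropped = n_zero, method = method))
  }
  if (n < 2L) stop("fewer than 2 informative pairs after dropping zeros")
  if (method == "permutation_t") {
    ## exact enumeration of sign flips of the observed differences
    stat <- mean(d)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- as.numeric(signs %*% d) / n
    p <- mean(abs(perm) >= abs(stat) - 1e-12)
    return(list(statistic = stat, p_value = p, n_used = n,
                n_zero_dropped = n_zero, method = method))
  }
  r <- rank(abs(d)) # midranks under ties
  W <- sum(r[d > 0])
  ## exact null via convolution on the doubled-rank integer grid
  g2 <- as.integer(round(2 * r))
  maxs <- sum(g2)
  dist <- numeric(maxs + 1L) # index k+1 = probability weight of 2W = k
  dist[1] <- 1
  for (v in g2) {
    shifted <- c(rep(0, v), dist[seq_len(maxs + 1L - v)])
    dist <- (dist + shifted) / 2
  }
  w2 <- as.integer(round(2 * W))
  p_low <- sum(dist[seq_len(w2 + 1L)])
  p_high <- sum(dist[(w2 + 1L):(maxs + 1L)])
  p <- min(1, 2 * min(p_low, p_high))
  list(statistic = W, p_value = p, n_used = n, n_zero_dropped = n_zero,
       method = method)
}

#' Read a measurements CSV
#'
#' Expects columns `subject`, `fiber`, `replicate` and either product amount
#' columns in moles (`h2_mol`, ..., `butyrate_mol`) or raw columns (gas mole
#' fractions `h2_frac`/`ch4_frac`/`co2_frac` with `headspace_L` and
#' `temperature_K`, and SCFA concentrations `acetate_mM`/... with `slurry_L`)
#' which are converted on read.
#'
#' @param path CSV path.
#' @param pressure_atm Headspace pressure for the ideal-gas conversion.
#' @return Data frame in the canonical mol layout.
#' @export
read_measurements <- function(path, pressure_atm = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "fiber", "replicate")
  if (!all(need %in% names(df))) stop("measurements need columns: ", paste(need, collapse = ", "))
  gases <- c(h2 = "h2", ch4 = "ch4", co2 = "co2")
  for (g in gases) {
    mol_col <- paste0(g, "_mol")
    frac_col <- paste0(g, "_frac")
    if (!mol_col %in% names(df) && frac_col %in% names(df)) {
      df[[mol_col]] <- headspace_moles(df[[frac_col]], df$headspace_L,
                                       df$temperature_K, pressure_atm)
    }
  }
  for (s in c("acetate", "propionate", "butyrate")) {
    mol_col <- paste0(s, "_mol")
    mm_col <- paste0(s, "_mM")
    if (!mol_col %in% names(df) && mm_col %in% names(df)) {
      df[[mol_col]] <- df[[mm_col]] / 1000 * df$slurry_L
    }
  }
  df
}
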