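#' Orthonormal null-space basis of a balance matrix
#'
#' QR-based null space (via [pracma::nullspace()]): columns are an orthonormal
#' basis B of null(M), so every balanced reaction vector is s = B x. The basis
#' dimension is n - rank(M).
#'
#' @param M A `balance_matrix` or a plain numeric matrix.
#' @return Numeric matrix with orthonormal columns (n x d), or a matrix with
#'   zero columns when the null space is trivial.
#' @examples
#' bm <- build_balance_matrix(c(list(monomer_species("inulin")), default_product_panel()))
#' ncol(null_space_basis(bm)) # 5
#' @export
null_space_basis <- function(M) {
  A <- if (inherits(M, "balance_matrix")) M$M else M
  B <- pracma::nullspace(A)
  if (is.null(B)) B <- matrix(0, ncol(A), 0)
  rownames(B) <- colnames(A)
  stopifnot(ncol(B) == 0 || max(abs(A %*% B)) <= 1e-10)
  B
}

#' Constraint configuration for a product polytope
#'
#' @param water_mode `"free"` (default): water may be consumed or produced,
#'   which the anhydro monomer convention requires (hydrolysis water);
#'   `"nonnegative"`: the strictly closed variant where even water cannot be
#'   taken up.
#' @param biomass_yield Optional fraction f in [0, 1) of substrate carbon fixed
#'   into biomass; pins the biomass coefficient at f * C_substrate / C_biomass
#'   per mole of substrate.
#' @param relaxed_inputs Optional named numeric vector of lower bounds (<= 0)
#'   for products allowed as inputs, e.g. `c(H2 = -10/3)`. Usually set via
#'   [relax_input()] rather than by hand.
#' @param substrate_amount Moles of substrate fixed into the system (default 1).
#' @param tol_eq Equality/feasibility tolerance (default 1e-9).
#' @param tol_dedup Vertex deduplication tolerance, infinity norm (default 1e-8).
#' @return A `polytope_config` list.
#' @export
polytope_config <- function(water_mode = c("free", "nonnegative"),
                            biomass_yield = NULL,
                            relaxed_inputs = NULL,
                            substrate_amount = 1,
                            tol_eq = 1e-9,
                            tol_dedup = 1e-8) {
  water_mode <- match.arg(water_mode)
  if (!is.null(biomass_yield)) {
    stopifnot(is.numeric(biomass_yield), length(biomass_yield) == 1L,
              biomass_yield >= 0, biomass_yield < 1)
  }
  if (!is.null(relaxed_inputs)) {
    if (is.null(names(relaxed_inputs)) || any(relaxed_inputs > 0)) {
      stop("relaxed_inputs must be a named vector of bounds <= 0")
    }
  }
  stopifnot(substrate_amount > 0, tol_eq >= 0, tol_dedup >= 0)
  structure(list(water_mode = water_mode, biomass_yield = biomass_yield,
                 relaxed_inputs = relaxed_inputs,
                 substrate_amount = substrate_amount,
                 tol_eq = tol_eq, tol_dedup = tol_dedup),
            class = "polytope_config")
}

## identify the biomass species: the unique N-bearing product column
.biomass_name <- function(bm) {
  has_n <- abs(bm$M["e", ] - (4 * bm$M["C", ] + bm$M["H", ] - 2 * bm$M["O", ])) > 1e-12 &
    bm$roles == "product"
  if (bm$electron_mode == "total_valence") {
    has_n <- abs(bm$M["e", ] - (4 * bm$M["C", ] + bm$M["H", ] + 6 * bm$M["O", ])) > 1e-12 &
      bm$roles == "product"
  }
  nm <- bm$species[has_n]
  if ("biomass" %in% bm$species) return("biomass")
  if (length(nm) == 1L) nm else NA_character_
}

## append an ammonia exchange column to an existing balance matrix
.add_nh3 <- function(bm) {
  if ("NH3" %in% bm$species) return(bm)
  e <- if (bm$electron_mode == "degree_of_reduction") 0 else 8
  bm$M <- cbind(bm$M, NH3 = c(0, 3, 0, e))
  bm$species <- c(bm$species, "NH3")
  bm$roles <- c(bm$roles, NH3 = "exchange")
  bm
}

#' Build the feasible product polytope (half-space stage)
#'
#' Assembles the affine system \{s : M s = 0, s_substrate = amount, bounds per
#' config\} for one batch of fiber. Products are constrained nonnegative (the
#' closed system); water is free by default; exchange species are always free;
#' relaxed inputs get negative lower bounds. When a biomass yield f is set, the
#' biomass coefficient is pinned so that biomass carbon equals f times
#' substrate carbon; because biomass carries nitrogen, this requires a nitrogen
#' source: in degree-of-reduction mode an NH3 exchange column (zero reducing
#' power) is added automatically, while in total-valence mode the build fails
#' unless the panel already contains one (the electron row otherwise forces
#' zero biomass).
#'
#' @param balance A `balance_matrix` from [build_balance_matrix()].
#' @param config A [polytope_config()].
#' @return A `product_polytope` object.
#' @seealso [fiber_polytope()] for the one-call constructor,
#'   [enumerate_vertices()], [max_product()], [check_feasibility()].
#' @export
build_polytope <- function(balance, config = polytope_config()) {
  stopifnot(inherits(balance, "balance_matrix"))
  if (!inherits(config, "polytope_config")) stop("config must come from polytope_config()")

  bio <- .biomass_name(balance)
  if (!is.null(config$biomass_yield) && config$biomass_yield > 0) {
    if (is.na(bio)) stop("no biomass (N-bearing product) species in the panel")
    n_source <- any(balance$roles == "exchange" & balance$species == "NH3")
    if (!n_source) {
      if (balance$electron_mode == "degree_of_reduction") {
        balance <- .add_nh3(balance)
      } else {
        stop("biomass yield is infeasible in total_valence mode without a ",
             "nitrogen source column: the electron row forces the biomass ",
             "coefficient to zero. Add an NH3 exchange species or use ",
             "degree_of_reduction mode.")
      }
    }
  }

  M <- balance$M
  nm <- balance$species
  n <- length(nm)
  roles <- balance$roles
  sub <- nm[roles == "substrate"]

  lb <- stats::setNames(rep(0, n), nm)
  lb[roles == "exchange"] <- -Inf
  if (config$water_mode == "free" && "H2O" %in% nm) lb["H2O"] <- -Inf
  if (!is.null(config$relaxed_inputs)) {
    bad <- setdiff(names(config$relaxed_inputs), nm)
    if (length(bad)) stop("relaxed input not in panel: ", paste(bad, collapse = ", "))
    lb[names(config$relaxed_inputs)] <- config$relaxed_inputs
  }

  Aeq <- rbind(M, as.numeric(nm == sub))
  beq <- c(rep(0, nrow(M)), config$substrate_amount)
  if (!is.null(config$biomass_yield)) {
    c_sub <- -M["C", sub]
    c_bio <- M["C", bio]
    pin <- config$biomass_yield * c_sub * config$substrate_amount / c_bio
    Aeq <- rbind(Aeq, as.numeric(nm == bio))
    beq <- c(beq, pin)
  }

  poly <- structure(
    list(balance = balance, config = config, lb = lb, Aeq = Aeq, beq = beq,
         substrate = sub, basis = null_space_basis(balance),
         cache = new.env(parent = emptyenv())),
    class = "product_polytope"
  )

  feas <- .lp(rep(0, n), Aeq = Aeq, beq = beq, lb = lb)
  if (feas$status != "optimal") {
    stop("infeasible constraint set (electron mode ", balance$electron_mode,
         if (!is.null(config$biomass_yield)) sprintf(", biomass yield %g", config$biomass_yield),
         "): no reaction vector satisfies all balances and bounds")
  }

  ## boundedness: with the substrate pinned, every coordinate must have a
  ## finite LP maximum (carbon bound for C species, electron bound for H2)
  bounded <- TRUE
  ray <- NULL
  for (j in seq_len(n)) {
    if (nm[j] == sub) next
    r <- .lp(as.numeric(nm == nm[j]), Aeq = Aeq, beq = beq, lb = lb, maximize = TRUE)
    if (r$status == "unbounded") {
      bounded <- FALSE
      ray <- stats::setNames(r$ray, nm)
      break
    }
    r2 <- .lp(as.numeric(nm == nm[j]), Aeq = Aeq, beq = beq, lb = lb, maximize = FALSE)
    if (r2$status == "unbounded") {
      bounded <- FALSE
      ray <- stats::setNames(r2$ray, nm)
      break
    }
  }
  poly$bounded <- bounded
  poly$ray <- ray
  poly
}

#' One-call product polytope for a fiber
#'
#' Convenience wrapper: builds the monomer substrate, the default product
#' panel, the balance matrix and the polytope in one step.
#'
#' @inheritParams monomer_species
#' @inheritParams build_balance_matrix
#' @param ... Passed to [polytope_config()].
#' @return A `product_polytope`.
#' @examples
#' p <- fiber_polytope("inulin")
#' max_product(p, "H2") # 12
#' @export
fiber_polytope <- function(fiber = c("inulin", "pectin"),
                           convention = c("anhydro", "monosaccharide"),
                           electron_mode = c("degree_of_reduction", "total_valence"),
                           ...) {
  species <- c(list(monomer_species(fiber, convention)), default_product_panel())
  build_polytope(build_balance_matrix(species, match.arg(electron_mode)),
                 polytope_config(...))
}

#' @export
print.product_polytope <- function(x, ...) {
  cat(sprintf(
    "<product_polytope> substrate %s (%g mol), %d species, electron mode %s\n",
    x$substrate, x$config$substrate_amount, length(x$lb), x$balance$electron_mode
  ))
  cat(sprintf("  water %s; affine dimension %d; bounded: %s\n",
              x$config$water_mode, .affine_dim(x), x$bounded))
  if (!is.null(x$config$biomass_yield)) {
    cat(sprintf("  biomass yield pinned at %g of substrate C\n", x$config$biomass_yield))
  }
  if (!is.null(x$config$relaxed_inputs)) {
    cat("  relaxed inputs:",
        paste(sprintf("%s >= %.4g", names(x$config$relaxed_inputs), x$config$relaxed_inputs),
              collapse = ", "), "\n")
  }
  invisible(x)
}

.affine_dim <- function(poly) {
  ncol(poly$Aeq) - qr(poly$Aeq)$rank
}

## affine parameterization s = s0 + N y of {Aeq s = beq}
.affine_basis <- function(Aeq, beq) {
  sv <- svd(Aeq, nu = nrow(Aeq), nv = ncol(Aeq))
  r <- sum(sv$d > max(dim(Aeq)) * .Machine$double.eps * sv$d[1])
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  s0 <- V %*% (crossprod(U, beq) / sv$d[seq_len(r)])
  N <- sv$v[, -seq_len(r), drop = FALSE]
  list(s0 = as.numeric(s0), N = N, rank = r)
}

#' Enumerate the vertices of a product polytope
#'
#' Exhaustive active-set search in the null-space coordinates: the affine
#' dimension d of \{Aeq s = beq\} is small (<= 6 for the shipped panels), so
#' every d-subset of the sign constraints is solved as a square system and
#' kept when feasible. Candidate solutions are checked against all constraints
#' at the equality tolerance and deduplicated at the dedup tolerance.
#'
#' @param poly A `product_polytope`.
#' @return Numeric matrix, one row per vertex, columns named by species.
#' @export
enumerate_vertices <- function(poly) {
  stopifnot(inherits(poly, "product_polytope"))
  if (!is.null(poly$cache$vertices)) return(poly$cache$vertices)
  if (!poly$bounded) {
    stop("polytope is unbounded; certificate ray available in poly$ray")
  }
  nm <- names(poly$lb)
  ab <- .affine_basis(poly$Aeq, poly$beq)
  d <- ncol(ab$N)
  if (d > 12L) stop("affine dimension ", d, " exceeds the intended scale (12)")
  tol <- poly$config$tol_eq
  fin <- which(is.finite(poly$lb))
  if (d == 0L) {
    s <- ab$s0
    if (any(s[fin] < poly$lb[fin] - tol)) return(matrix(numeric(0), 0, length(nm), dimnames = list(NULL, nm)))
    V <- matrix(s, 1, dimnames = list(NULL, nm))
    poly$cache$vertices <- V
    return(V)
  }
  A <- ab$N[fin, , drop = FALSE]
  bnd <- poly$lb[fin] - ab$s0[fin]
  mI <- length(fin)
  if (mI < d) stop("fewer inequality constraints than dimensions; polytope cannot be bounded")
  verts <- list()
  for (idx in utils::combn(mI, d, simplify = FALSE)) {
    Asub <- A[idx, , drop = FALSE]
    if (abs(det(Asub)) < 1e-10) next
    y <- solve(Asub, bnd[idx])
    if (all(A %*% y - bnd >= -tol)) {
      verts[[length(verts) + 1L]] <- as.numeric(ab$s0 + ab$N %*% y)
    }
  }
  out <- list()
  for (v in verts) {
    dup <- FALSE
    for (w in out) if (max(abs(v - w)) < poly$config$tol_dedup) { dup <- TRUE; break }
    if (!dup) out[[length(out) + 1L]] <- v
  }
  V <- do.call(rbind, c(out, list(matrix(numeric(0), 0, length(nm)))))
  colnames(V) <- nm
  poly$cache$vertices <- V
  V
}

#' Maximum (or minimum) of a product over the feasible set
#'
#' Linear program over the polytope. Optionally pins other coordinates first
#' (e.g. the minimum CO2 coproduced at maximum acetate).
#'
#' @param poly A `product_polytope`.
#' @param product Species name.
#' @param maximize Maximize (default) or minimize.
#' @param fixed Optional named numeric vector of coordinates to pin.
#' @return Moles of product per batch; `Inf` (with a warning) if unbounded.
#' @examples
#' max_product(fiber_polytope("pectin"), "H2") # 10
#' @export
max_product <- function(poly, product, maximize = TRUE, fixed = NULL) {
  stopifnot(inherits(poly, "product_polytope"))
  nm <- names(poly$lb)
  if (!product %in% nm) stop("unknown product: ", product)
  Aeq <- poly$Aeq
  beq <- poly$beq
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), nm)
    if (length(bad)) stop("unknown fixed product: ", paste(bad, collapse = ", "))
    for (p in names(fixed)) {
      Aeq <- rbind(Aeq, as.numeric(nm == p))
      beq <- c(beq, fixed[[p]])
    }
  }
  r <- .lp(as.numeric(nm == product), Aeq = Aeq, beq = beq, lb = poly$lb,
           maximize = maximize)
  if (r$status == "unbounded") {
    warning("objective unbounded for ", product)
    return(if (maximize) Inf else -Inf)
  }
  if (r$status != "optimal") stop("LP ", r$status, " when optimizing ", product)
  r$value
}

#' 2D convex-hull projection of the product polytope
#'
#' Projects the enumerated vertex set onto two product coordinates and returns
#' the convex hull (counterclockwise vertex order). Degenerate hulls (segment
#' or point) are returned as such.
#'
#' @param poly A `product_polytope`.
#' @param product_i,product_j Two product names (may coincide, giving the
#'   diagonal segment).
#' @return List with `hull` (matrix of hull vertices, 2 columns), `degenerate`
#'   (TRUE for a segment or point) and `products`.
#' @export
project_2d <- function(poly, product_i, product_j) {
  nm <- names(poly$lb)
  if (!all(c(product_i, product_j) %in% nm)) stop("unknown product(s)")
  V <- enumerate_vertices(poly)
  P <- cbind(V[, product_i], V[, product_j])
  colnames(P) <- c(product_i, product_j)
  if (nrow(P) == 0L) return(list(hull = P, degenerate = TRUE, products = c(product_i, product_j)))
  uniq <- P[!duplicated(round(P, 10)), , drop = FALSE]
  if (nrow(uniq) <= 2L) {
    return(list(hull = uniq, degenerate = TRUE, products = c(product_i, product_j)))
  }
  ## collinearity check
  d1 <- uniq[2, ] - uniq[1, ]
  cross <- apply(uniq[-1, , drop = FALSE], 1, function(p) {
    d <- p - uniq[1, ]
    d1[1] * d[2] - d1[2] * d[1]
  })
  if (all(abs(cross) < 1e-10)) {
    proj <- as.numeric(uniq %*% d1)
    seg <- uniq[c(which.min(proj), which.max(proj)), , drop = FALSE]
    return(list(hull = seg, degenerate = TRUE, products = c(product_i, product_j)))
  }
  h <- grDevices::chull(uniq)
  list(hull = uniq[h, , drop = FALSE], degenerate = FALSE,
       products = c(product_i, product_j))
}

#' Feasibility of a measured product profile
#'
#' Asks whether a full balanced reaction vector exists whose coordinates match
#' the measured values within `tolerance`; unmeasured species (typically water
#' and biomass) are left free within the polytope's own bounds. Unmeasured is
#' not zero: pass explicit zeros for products known to be absent. When the
#' profile is infeasible the report carries the minimal uniform slack (the
#' infinity-norm inflation of the measurement band) that admits it.
#'
#' @param poly A `product_polytope`.
#' @param measured Named numeric vector of measured mol-per-mol-fiber values.
#' @param tolerance Half-width of the measurement band (>= 0; default 1e-9).
#' @return A `feasibility_report`: list with `feasible`, `witness` (a full
#'   reaction vector, or the closest completion when infeasible), `slack`
#'   (0 when feasible), `tolerance`.
#' @export
check_feasibility <- function(poly, measured, tolerance = 1e-9) {
  stopifnot(inherits(poly, "product_polytope"))
  if (tolerance < 0) stop("tolerance must be >= 0")
  nm <- names(poly$lb)
  if (is.null(names(measured)) || !all(names(measured) %in% nm)) {
    stop("measured must be named by species in the panel")
  }
  n <- length(nm)
  mi <- match(names(measured), nm)
  ## band rows: s_i <= m_i + tol ; -s_i <= -(m_i - tol)
  E <- diag(n)[mi, , drop = FALSE]
  Ale <- rbind(E, -E)
  ble <- c(measured + tolerance, -(measured - tolerance))
  r <- .lp(rep(0, n), Aeq = poly$Aeq, beq = poly$beq, Ale = Ale, ble = ble,
           lb = poly$lb)
  if (r$status == "optimal") {
    return(structure(list(feasible = TRUE, witness = stats::setNames(r$s, nm),
                          slack = 0, tolerance = tolerance),
                     class = "feasibility_report"))
  }
  ## minimal uniform slack t: bands widen to m_i +- (tol + t)
  v <- c(rep(0, n), 1)
  Aeq2 <- cbind(poly$Aeq, 0)
  Ale2 <- rbind(cbind(E, -1), cbind(-E, -1))
  ble2 <- c(measured + tolerance, -(measured - tolerance))
  lb2 <- c(poly$lb, 0)
  r2 <- .lp(v, Aeq = Aeq2, beq = poly$beq, Ale = Ale2, ble = ble2, lb = lb2,
            maximize = FALSE)
  if (r2$status != "optimal") stop("slack LP failed: ", r2$status)
  structure(list(feasible = FALSE,
                 witness = stats::setNames(r2$s[seq_len(n)], nm),
                 slack = r2$value, tolerance = tolerance),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(sprintf("<feasibility_report> feasible: %s (tolerance %.3g)\n",
              x$feasible, x$tolerance))
  if (!x$feasible) cat(sprintf("  minimal uniform slack: %.6g\n", x$slack))
  cat("  witness completion:\n")
  print(round(x$witness, 6))
  invisible(x)
}

#' Allow one product as an input from the surrounding environment
#'
#' Relaxes the lower bound of a single product to minus `fraction` times the
#' closed-system maximum of that product for the same substrate amount; the
#' default fraction 1/3 mirrors the observation that no-fiber controls produce
#' about one third as much gas and SCFA as treated samples, so the residual
#' slurry can supply at most that much of any one product. The relaxed
#' feasible set contains the original.
#'
#' @param poly A `product_polytope`.
#' @param product Product to allow as input.
#' @param fraction Positive fraction of the closed-system per-product maximum
#'   (default 1/3).
#' @param bound Optional explicit bound (mol) overriding the computed one,
#'   e.g. an observed control output.
#' @return A new `product_polytope` with the relaxed bound.
#' @examples
#' p <- relax_input(fiber_polytope("pectin"), "H2")
#' max_product(p, "butyrate") # 4/3
#' @export
relax_input <- function(poly, product, fraction = 1 / 3, bound = NULL) {
  stopifnot(inherits(poly, "product_polytope"), fraction > 0)
  nm <- names(poly$lb)
  if (!product %in% nm) stop("unknown product: ", product)
  cfg <- poly$config
  if (is.null(bound)) {
    base_cfg <- cfg
    base_cfg$relaxed_inputs <- NULL
    base <- build_polytope(poly$balance, base_cfg)
    closed_max <- max_product(base, product)
    bound <- fraction * closed_max
    if (closed_max <= 0) {
      warning("closed-system maximum of ", product, " is 0; relaxation is a no-op")
    }
  }
  cfg$relaxed_inputs <- c(cfg$relaxed_inputs,
                          stats::setNames(-abs(bound), product))
  cfg$relaxed_inputs <- cfg$relaxed_inputs[!duplicated(names(cfg$relaxed_inputs), fromLast = TRUE)]
  build_polytope(poly$balance, cfg)
}

#' Pin the biomass yield of the fermentation
#'
#' Fixes the biomass coefficient so that biomass carbon equals `f` times the
#' substrate carbon (the literature value for a typical carbohydrate
#' fermentation is f = 0.15). The constrained feasible set is a subset of the
#' unconstrained one. See [build_polytope()] for the nitrogen-source handling.
#'
#' @param poly A `product_polytope`.
#' @param f Fraction of substrate carbon fixed into biomass, in [0, 1).
#' @return A new `product_polytope`.
#' @examples
#' p <- apply_biomass_yield(fiber_polytope("inulin"), 0.15)
#' max_product(p, "H2") # 10.11
#' @export
apply_biomass_yield <- function(poly, f) {
  stopifnot(inherits(poly, "product_polytope"), f >= 0, f < 1)
  cfg <- poly$config
  cfg$biomass_yield <- if (f == 0) NULL else f
  build_polytope(poly$balance, cfg)
}

#' Export a polytope to JSON
#'
#' Writes matrix, configuration, vertices and per-product maxima in a plain
#' JSON structure suitable for plotting pipelines.
#'
#' @param poly A `product_polytope`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_polytope_json <- function(poly, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON export")
  }
  nm <- names(poly$lb)
  prods <- nm[poly$balance$roles[nm] == "product"]
  obj <- list(
    species = nm,
    matrix = unname(poly$balance$M),
    electron_mode = poly$balance$electron_mode,
    config = unclass(poly$config),
    vertices = unname(enumerate_vertices(poly)),
    maxima = as.list(stats::setNames(
      vapply(prods, function(p) max_product(poly, p), 0), prods))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
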