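#' @keywords internal
"_PACKAGE"

## Elements supported by the balance model. Valence electron counts are fixed:
## any other element is an error rather than a guess.
.ELEMENTS <- c("C", "H", "O", "N")
.VALENCE <- c(C = 4, H = 1, O = 6, N = 5)
## degree-of-reduction weights: available electrons relative to CO2/H2O/NH3
.GAMMA <- c(C = 4, H = 1, O = -2, N = -3)
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

#' Parse a chemical formula string
#'
#' Reads a formula composed of the element symbols C, H, O and N, each
#' optionally followed by a (possibly fractional) count, e.g. `"C6H10O5"` or
#' the mean microbial biomass formula `"CH1.8O0.5N0.2"`. Counts are taken
#' exactly as written; no normalization is applied.
#'
#' @param text A single formula string.
#' @return Named numeric vector with entries `C`, `H`, `O`, `N` (absent
#'   elements are 0).
#' @examples
#' parse_formula("C6H10O5")
#' parse_formula("CH1.8O0.5N0.2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string")
  }
  tokens <- gregexpr("[A-Za-z][0-9.]*", text)[[1]]
  pieces <- regmatches(text, gregexpr("[A-Za-z][0-9.]*", text))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(text)) {
    stop("malformed formula: ", text)
  }
  counts <- stats::setNames(rep(0, length(.ELEMENTS)), .ELEMENTS)
  for (p in pieces) {
    el <- substr(p, 1, 1)
    if (!el %in% .ELEMENTS) stop("unknown element symbol: ", el)
    num <- substr(p, 2, nchar(p))
    cnt <- if (nzchar(num)) suppressWarnings(as.numeric(num)) else 1
    if (is.na(cnt) || cnt < 0) stop("malformed count in formula: ", p)
    counts[el] <- counts[el] + cnt
  }
  if (all(counts == 0)) stop("formula has no atoms: ", text)
  counts
}

#' Total valence electrons of a species
#'
#' Counts 4 per C, 1 per H, 6 per O and 5 per N, the "electrons as an extra
#' element" bookkeeping used in the balance matrix.
#'
#' @param element_counts Named numeric vector as returned by [parse_formula()].
#' @return Electron count (numeric scalar).
#' @examples
#' valence_electrons(parse_formula("C6H12O6")) # 72
#' @export
valence_electrons <- function(element_counts) {
  element_counts <- .check_counts(element_counts)
  sum(.VALENCE * element_counts)
}

#' Degree of reduction of a species
#'
#' Available electrons per mole relative to the reference compounds CO2, H2O
#' and NH3: 4C + H - 2O - 3N. Zero for CO2 and water; 24 for glucose. This is
#' the electron functional under which ammonia carries no reducing power, so
#' nitrogen assimilation into biomass does not perturb the electron balance.
#'
#' @inheritParams valence_electrons
#' @return Electron count (numeric scalar).
#' @examples
#' degree_of_reduction(parse_formula("C6H12O6")) # 24
#' degree_of_reduction(parse_formula("CO2"))     # 0
#' @export
degree_of_reduction <- function(element_counts) {
  element_counts <- .check_counts(element_counts)
  sum(.GAMMA * element_counts)
}

.check_counts <- function(x) {
  if (is.null(names(x))) stop("element counts must be named")
  if (!all(names(x) %in% .ELEMENTS)) {
    stop("unknown element(s): ", paste(setdiff(names(x), .ELEMENTS), collapse = ", "))
  }
  if (any(x < 0) || all(x == 0)) stop("counts must be nonnegative with at least one positive")
  full <- stats::setNames(rep(0, length(.ELEMENTS)), .ELEMENTS)
  full[names(x)] <- x
  full
}

#' Define a chemical species
#'
#' @param name Species label (must be unique within a panel).
#' @param formula Formula string, parsed by [parse_formula()].
#' @param role One of `"substrate"`, `"product"`, `"exchange"`. Exchange
#'   species have unconstrained sign (both uptake and release allowed).
#' @return A `chemical_species` object.
#' @examples
#' chemical_species("biomass", "CH1.8O0.5N0.2", "product")
#' @export
chemical_species <- function(name, formula, role = c("product", "substrate", "exchange")) {
  role <- match.arg(role)
  structure(
    list(name = name, element_counts = parse_formula(formula), role = role),
    class = "chemical_species"
  )
}

#' @export
print.chemical_species <- function(x, ...) {
  ec <- x$element_counts[x$element_counts > 0]
  cat(sprintf(
    "<chemical_species> %s (%s): %s; gamma = %g, valence e = %g\n",
    x$name, x$role, paste0(names(ec), ec, collapse = ""),
    degree_of_reduction(x$element_counts), valence_electrons(x$element_counts)
  ))
  invisible(x)
}

#' Monomer species for a fiber
#'
#' The polymer formulas are C6nH10n+2O5n+1 (inulin, a fructan) and
#' C6nH8n+2O6n+1 (pectin, a galacturonan). Two per-mole conventions are
#' supported: `"anhydro"` takes the per-repeat-unit limit of the polymer
#' formula (inulin C6H10O5, pectin C6H8O6), i.e. the glycosyl residue lacking
#' one hydrolysis water; `"monosaccharide"` substitutes n = 1 (free fructose
#' C6H12O6, free galacturonic acid C6H10O7).
#'
#' @param fiber `"inulin"` or `"pectin"`.
#' @param convention `"anhydro"` (default) or `"monosaccharide"`.
#' @return A `chemical_species` with role `"substrate"`.
#' @examples
#' monomer_species("inulin")
#' monomer_species("pectin", "monosaccharide")
#' @export
monomer_species <- function(fiber = c("inulin", "pectin"),
                            convention = c("anhydro", "monosaccharide")) {
  fiber <- match.arg(fiber)
  convention <- match.arg(convention)
  formula <- switch(convention,
    anhydro = switch(fiber, inulin = "C6H10O5", pectin = "C6H8O6"),
    monosaccharide = switch(fiber, inulin = "C6H12O6", pectin = "C6H10O7")
  )
  chemical_species(fiber, formula, "substrate")
}

#' Molar mass of a species
#'
#' @param species A `chemical_species` or a named element-count vector.
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(species) {
  counts <- if (inherits(species, "chemical_species")) species$element_counts else .check_counts(species)
  sum(.ATOMIC_MASS * counts)
}

#' Default fermentation product panel
#'
#' The three most abundant gut SCFAs (acetate, propionate, butyrate as neutral
#' acids), the three major intestinal gases (H2, CH4, CO2), water and microbial
#' biomass (mean formula CH1.8O0.5N0.2).
#'
#' @return List of `chemical_species` with role `"product"`.
#' @export
default_product_panel <- function() {
  list(
    chemical_species("acetate", "C2H4O2"),
    chemical_species("propionate", "C3H6O2"),
    chemical_species("butyrate", "C4H8O2"),
    chemical_species("H2", "H2"),
    chemical_species("CH4", "CH4"),
    chemical_species("CO2", "CO2"),
    chemical_species("H2O", "H2O"),
    chemical_species("biomass", "CH1.8O0.5N0.2")
  )
}

#' Read a species panel from a config file
#'
#' Plain CSV with columns `name`, `formula`, `role`.
#'
#' @param path Path to the CSV file.
#' @return List of `chemical_species`.
#' @export
read_species_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "role")
  if (!all(need %in% names(df))) stop("species panel needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) chemical_species(df$name[i], df$formula[i], df$role[i]))
}

#' Build the elemental and electron balance matrix
#'
#' Constructs the 4 x n matrix M whose rows are C, H, O and electrons and whose
#' columns are the species of the system. The substrate column is negated
#' (inputs negative, outputs positive), so a balanced reaction is any
#' coefficient vector s with M s = 0 and a positive substrate coefficient.
#' The electron row applies the configured electron functional to each
#' column's element counts.
#'
#' Note that for nitrogen-free species both electron functionals are linear
#' combinations of the three mass rows (gamma = 4C + H - 2O, total valence =
#' 4C + H + 6O); the electron row carries independent information exactly
#' where nitrogen enters the system (the biomass column, and an NH3 exchange
#' column if present). A consequence documented in the package vignette: with
#' no nitrogen source in the panel the electron balance pins the biomass
#' coefficient at zero in either mode.
#'
#' @param species List of `chemical_species`; exactly one must have role
#'   `"substrate"`.
#' @param electron_mode `"degree_of_reduction"` (default) or `"total_valence"`.
#' @return A `balance_matrix` object: list with `M` (4 x n numeric, rows
#'   C/H/O/e), `species` (names), `roles`, `electron_mode` and
#'   `sign_convention = "inputs_negative"`.
#' @examples
#' bm <- build_balance_matrix(c(list(monomer_species("inulin")), default_product_panel()))
#' bm$M[, "H2"]
#' @export
build_balance_matrix <- function(species,
                                 electron_mode = c("degree_of_reduction", "total_valence")) {
  electron_mode <- match.arg(electron_mode)
  if (!length(species) || !all(vapply(species, inherits, TRUE, "chemical_species"))) {
    stop("species must be a list of chemical_species")
  }
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate species names: ", paste(nm[duplicated(nm)], collapse = ", "))
  roles <- vapply(species, `[[`, "", "role")
  n_sub <- sum(roles == "substrate")
  if (n_sub != 1L) stop("exactly one substrate species required, got ", n_sub)
  efun <- if (electron_mode == "degree_of_reduction") degree_of_reduction else valence_electrons
  M <- vapply(species, function(sp) {
    ec <- sp$element_counts
    c(ec[["C"]], ec[["H"]], ec[["O"]], efun(ec))
  }, numeric(4))
  dimnames(M) <- list(c("C", "H", "O", "e"), nm)
  M[, roles == "substrate"] <- -M[, roles == "substrate"]
  structure(
    list(M = M, species = nm, roles = stats::setNames(roles, nm),
         electron_mode = electron_mode, sign_convention = "inputs_negative"),
    class = "balance_matrix"
  )
}

#' @export
print.balance_matrix <- function(x, ...) {
  cat(sprintf("<balance_matrix> %d species, electron mode: %s\n", length(x$species), x$electron_mode))
  print(round(x$M, 4))
  invisible(x)
}
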