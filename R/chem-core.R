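# Elemental-composition arithmetic, monoisotopic masses, ion conventions.
#
# All compositions in this package are data frames carrying the six integer
# columns c, h, o, s, na, n13c (n13c = number of 13C substitutions). Extra
# columns are carried along untouched, so annotation tables can be fed
# directly into the mass functions.

#' Monoisotopic atomic masses
#'
#' Isotope masses in unified atomic mass units (u), taken from the AME2020
#' atomic mass evaluation (Wang et al. 2021, Chinese Phys. C 45, 030003);
#' proton and electron masses from CODATA 2018. Stored to >= 9 decimal
#' places so that reaction mass differences quoted at 5 d.p. are exact.
#'
#' @format Named numeric vector with elements `C12`, `C13`, `H1`, `O16`,
#'   `S32`, `S34`, `Na23`, `proton`, `electron`.
#' @export
atomic_masses <- c(
  C12      = 12.0,
  C13      = 13.003354835,
  H1       = 1.007825031898,
  O16      = 15.994914619257,
  S32      = 31.972071174,
  S34      = 33.967867012,
  Na23     = 22.989769282,
  proton   = 1.007276466621,
  electron = 0.000548579909
)

#' Mass shift of one 13C substitution (u)
#' @export
delta_13c <- unname(atomic_masses["C13"] - atomic_masses["C12"])

#' Mass shift of one 34S substitution (u)
#' @export
delta_34s <- unname(atomic_masses["S34"] - atomic_masses["S32"])

.comp_cols <- c("c", "h", "o", "s", "na", "n13c")

#' Create an elemental composition
#'
#' @param c,h,o,s,na Non-negative integer element counts (carbon, hydrogen,
#'   oxygen, sulfur, sodium).
#' @param n13c Number of carbon atoms substituted by 13C (`0 <= n13c <= c`).
#' @return One-row data frame with columns `c`, `h`, `o`, `s`, `na`, `n13c`.
#' @examples
#' comp(c = 2, h = 4, o = 2)            # acetic acid composition
#' comp(c = 2, h = 4, o = 2, n13c = 1)  # with one 13C substitution
#' @export
comp <- function(c = 0L, h = 0L, o = 0L, s = 0L, na = 0L, n13c = 0L) {
  out <- data.frame(c = as.integer(c), h = as.integer(h), o = as.integer(o),
                    s = as.integer(s), na = as.integer(na),
                    n13c = as.integer(n13c))
  validate_comp(out)
  out
}

#' @keywords internal
validate_comp <- function(x) {
  stopifnot(all(.comp_cols %in% names(x)))
  m <- as.matrix(x[.comp_cols])
  if (any(m < 0)) stop("element counts must be non-negative")
  if (any(x$n13c > x$c)) stop("n13c cannot exceed the carbon count")
  invisible(x)
}

#' Element-wise composition arithmetic
#'
#' `comp_add()` and `comp_sub()` add or subtract compositions element-wise;
#' both recycle a one-row composition against a many-row one. Subtraction
#' that would produce a negative count is an error.
#'
#' @param a,b Composition data frames (see [comp()]).
#' @return Composition data frame.
#' @export
comp_add <- function(a, b) {
  out <- a
  for (col in .comp_cols) out[[col]] <- a[[col]] + b[[col]]
  validate_comp(out[.comp_cols])
  out
}

#' @rdname comp_add
#' @export
comp_sub <- function(a, b) {
  out <- a
  for (col in .comp_cols) out[[col]] <- a[[col]] - b[[col]]
  if (any(as.matrix(out[.comp_cols]) < 0) || any(out$n13c > out$c))
    stop("composition subtraction produced a negative count")
  out
}

#' Monoisotopic mass of a composition
#'
#' Sum of count times isotope mass over all elements; 13C substitutions are
#' counted at the 13C mass. Vectorized over the rows of `x`.
#'
#' @param x Composition data frame (columns `c`, `h`, `o`, `s`, `na`, `n13c`).
#' @return Numeric vector of masses in u.
#' @examples
#' monoisotopic_mass(comp(c = 2, h = 2))  # acetylene, 26.01565
#' @export
monoisotopic_mass <- function(x) {
  validate_comp(x)
  (x$c - x$n13c) * atomic_masses[["C12"]] +
    x$n13c * atomic_masses[["C13"]] +
    x$h * atomic_masses[["H1"]] +
    x$o * atomic_masses[["O16"]] +
    x$s * atomic_masses[["S32"]] +
    x$na * atomic_masses[["Na23"]]
}

#' Exact mass of a reaction (transformation) difference
#'
#' The mass of the elemental difference added by a reaction edge; identical
#' to [monoisotopic_mass()] of the delta composition.
#'
#' @param delta Composition data frame.
#' @return Numeric vector of masses in u.
#' @export
transformation_mass <- function(delta) monoisotopic_mass(delta)

#' m/z of a singly charged negative ion
#'
#' Two negative-mode ion types are supported: `"deprotonated"` (\[M-H\]-,
#' m/z = M - m_proton) and `"sodiated-deprotonated"` (\[M-2H+Na\]-,
#' m/z = M - 2 m_proton + m(Na+)). Subtracting the proton mass (rather than
#' the hydrogen-atom mass) accounts for the electron implicitly.
#'
#' @param x Composition data frame.
#' @param ion `"deprotonated"` or `"sodiated-deprotonated"`.
#' @return Numeric vector of m/z values (charge -1).
#' @export
ion_mz <- function(x, ion = c("deprotonated", "sodiated-deprotonated")) {
  ion <- match.arg(ion)
  m <- monoisotopic_mass(x)
  if (ion == "deprotonated") {
    if (any(x$h < 1)) stop("deprotonation requires at least one hydrogen")
    m - atomic_masses[["proton"]]
  } else {
    if (any(x$h < 2)) stop("[M-2H+Na]- requires at least two hydrogens")
    m - 2 * atomic_masses[["proton"]] +
      (atomic_masses[["Na23"]] - atomic_masses[["electron"]])
  }
}

#' Elemental ratios H/C and O/C
#'
#' @param x Composition data frame with `c > 0`.
#' @return Data frame with columns `hc` and `oc`.
#' @export
ratios <- function(x) {
  if (any(x$c <= 0)) stop("H/C and O/C are undefined for c = 0")
  data.frame(hc = x$h / x$c, oc = x$o / x$c)
}

# ---- formula strings --------------------------------------------------------

#' Format compositions as formula strings
#'
#' Hill-like plain-text syntax used in all CSV columns: carbon then hydrogen
#' then remaining elements alphabetically (`"C6H10O4S"`), with a `[13Ck]`
#' prefix for k 13C substitutions (`"[13C2]C4H6O4"`). Round-trips through
#' [parse_formula()].
#'
#' @param x Composition data frame.
#' @return Character vector.
#' @export
format_formula <- function(x) {
  validate_comp(x)
  piece <- function(sym, n) ifelse(n == 0, "",
                                   ifelse(n == 1, sym, paste0(sym, n)))
  out <- paste0(
    ifelse(x$n13c > 0, paste0("[13C", ifelse(x$n13c > 1, x$n13c, ""), "]"), ""),
    piece("C", x$c), piece("H", x$h), piece("Na", x$na),
    piece("O", x$o), piece("S", x$s)
  )
  ifelse(nchar(out) == 0, "", out)
}

#' Parse formula strings into compositions
#'
#' @param x Character vector in the syntax of [format_formula()]. Element
#'   order is free; unknown element symbols are an error.
#' @return Composition data frame, one row per input string.
#' @export
parse_formula <- function(x) {
  parse_one <- function(f) {
    counts <- c(c = 0L, h = 0L, o = 0L, s = 0L, na = 0L, n13c = 0L)
    f <- trimws(f)
    lab <- regmatches(f, regexec("^\\[13C([0-9]*)\\]", f))[[1]]
    if (length(lab)) {
      counts["n13c"] <- if (nzchar(lab[2])) as.integer(lab[2]) else 1L
      f <- sub("^\\[13C[0-9]*\\]", "", f)
    }
    m <- gregexpr("(Na|C|H|O|S)([0-9]*)", f)[[1]]
    if (m[1] == -1 && nzchar(f)) stop("cannot parse formula: ", f)
    toks <- regmatches(f, gregexpr("(Na|C|H|O|S)([0-9]*)", f))[[1]]
    if (sum(nchar(toks)) != nchar(f)) stop("cannot parse formula: ", f)
    for (tok in toks) {
      sym <- regmatches(tok, regexpr("^(Na|C|H|O|S)", tok))
      n <- sub("^(Na|C|H|O|S)", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (n < 0) stop("negative element count in formula: ", f)
      key <- tolower(sym)
      counts[key] <- counts[key] + n
    }
    counts
  }
  res <- t(vapply(x, parse_one, integer(6)))
  out <- as.data.frame(res)
  names(out) <- .comp_cols
  rownames(out) <- NULL
  validate_comp(out)
  out
}

# ---- reaction transformation table ------------------------------------------

#' The six reaction mass differences used as network edges
#'
#' Reactions plausible in the acetylene/CO/H2O/NiS system, used both as
#' edges of the molecular network and as the propagation steps of the
#' mass-difference-network formula assignment: water addition (+H2O),
#' hydrogen sulfide addition (+H2S), dimerization/oligomerization (+C2H2),
#' carbonylation with H2O (+CH2O2), carbonylation with H2S (+CH2OS), and
#' reduction (+H2). The two carbonylations introduce one CO-derived carbon.
#'
#' @param names Optional subset of transformation names to return.
#' @return Data frame with columns `name`, `formula`, the delta composition
#'   columns, `delta_mass` (u), and `adds_co_carbon` (logical).
#' @examples
#' transformations()$delta_mass
#' @export
transformations <- function(names = NULL) {
  def <- data.frame(
    name = c("water_addition", "h2s_addition", "c2h2_addition",
             "carbonylation_h2o", "carbonylation_h2s", "reduction"),
    formula = c("H2O", "H2S", "C2H2", "CH2O2", "CH2OS", "H2"),
    stringsAsFactors = FALSE
  )
  def <- cbind(def, parse_formula(def$formula))
  def$delta_mass <- transformation_mass(def)
  def$adds_co_carbon <- def$name %in% c("carbonylation_h2o", "carbonylation_h2s")
  if (!is.null(names)) {
    stopifnot(all(names %in% def$name))
    def <- def[match(names, def$name), , drop = FALSE]
    rownames(def) <- NULL
  }
  def
}

# ---- small shared helpers ---------------------------------------------------

#' Parts-per-million difference between observed and theoretical values
#' @param observed,theoretical Numeric vectors.
#' @return (observed - theoretical) / theoretical * 1e6.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}

# Deterministic small-integer seed derived from a base seed and string tags,
# so that every stage/replicate has an independent reproducible RNG stream.
derive_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
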