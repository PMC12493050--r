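#' Model variants
#'
#' The package implements four reinforcement-learning drift diffusion model
#' (RLDDM) variants that share the delta-rule value update and the Wiener
#' first passage time likelihood, and differ in how the drift rate and the
#' boundary separation evolve over trials:
#'
#' * `RLDDM` - constant boundary `a`; drift `(Q_upper - Q_lower) * nu`.
#' * `RLDDM_drpow` - constant boundary; drift
#'   `(Q_upper - Q_lower) * (t/10)^p`, i.e. the drift scaling follows a power
#'   of the within-condition trial index (the scalar `nu` is dropped unless
#'   `include_nu = TRUE` is requested where supported).
#' * `RLDDM_bspow` - boundary `bb * (t/10)^bp` (collapsing for `bp < 0`,
#'   expanding for `bp > 0`); drift as in the base model.  This is the
#'   winning model used by default in downstream analyses.
#' * `RLDDM_bspow_drpow` - both modifications.
#'
#' `t` is the 1-based trial index within each trial type, so the power terms
#' equal 1 at the tenth trial of each condition.  The starting point is fixed
#' at `z = 0.5` throughout (stimulus sides are randomized), and neutral
#' trials use a fixed value difference of 0.4.
#'
#' @return `rlddm_variants()` returns the four variant names;
#'   `winning_variant()` returns `"RLDDM_bspow"`.
#' @examples
#' rlddm_variants()
#' winning_variant()
#' @export
rlddm_variants <- function() {
  c("RLDDM", "RLDDM_drpow", "RLDDM_bspow", "RLDDM_bspow_drpow")
}

#' @rdname rlddm_variants
#' @export
winning_variant <- function() "RLDDM_bspow"

# canonical slot order used by the C++ core:
# alpha = 1, nu = 2, bnd (a or bb) = 3, bp = 4, p = 5, t_nd = 6
CANON_SLOTS <- c(alpha = 1L, nu = 2L, a = 3L, bb = 3L, bp = 4L, p = 5L,
                 t_nd = 6L)
# transform codes: 0 logit, 1 log, 2 identity
CANON_TRANS <- c(alpha = 0L, nu = 1L, a = 1L, bb = 1L, bp = 2L, p = 2L,
                 t_nd = 1L)

match_variant <- function(variant) {
  match.arg(variant, rlddm_variants())
}

#' Free parameters and structure of a model variant
#'
#' @param variant one of [rlddm_variants()].
#' @param include_nu keep the drift-rate scalar `nu` multiplicatively in the
#'   drift-power variants.  The default `FALSE` follows the model definition
#'   in which the power term replaces the scalar.
#' @return a list with elements `name`, `drpow`, `bspow`, and `free` (the
#'   names of the variant's free parameters, in canonical order).
#' @examples
#' variant_info("RLDDM_bspow")$free
#' @export
variant_info <- function(variant, include_nu = FALSE) {
  variant <- match_variant(variant)
  drpow <- variant %in% c("RLDDM_drpow", "RLDDM_bspow_drpow")
  bspow <- variant %in% c("RLDDM_bspow", "RLDDM_bspow_drpow")
  free <- c("alpha",
            if (!drpow || include_nu) "nu",
            if (bspow) c("bb", "bp") else "a",
            if (drpow) "p",
            "t_nd")
  list(name = variant, drpow = drpow, bspow = bspow, free = free)
}

#' Subject-level RLDDM parameters
#'
#' Bundles and validates the free parameters of one subject for a given model
#' variant.  The starting-point fraction is always fixed at `z = 0.5`.
#'
#' @param variant one of [rlddm_variants()].
#' @param alpha learning rate, in (0, 1).
#' @param nu drift-rate scalar (> 0); ignored by the drift-power variants
#'   unless `include_nu = TRUE`.
#' @param a boundary separation (> 0) for the constant-boundary variants.
#' @param bb boundary-separation baseline (> 0) for the boundary-power
#'   variants.
#' @param bp boundary-separation power (real; negative values give a
#'   collapsing boundary).
#' @param p drift-rate power (real).
#' @param t_nd non-decision time in seconds (> 0).
#' @param include_nu see [variant_info()].
#' @return an object of class `subject_params`.
#' @examples
#' subject_params("RLDDM_bspow", alpha = 0.3, nu = 3, bb = 1.2, bp = -0.2,
#'                t_nd = 0.35)
#' @export
subject_params <- function(variant, alpha, nu = NULL, a = NULL, bb = NULL,
                           bp = NULL, p = NULL, t_nd, include_nu = FALSE) {
  info <- variant_info(variant, include_nu)
  vals <- list(alpha = alpha, nu = nu, a = a, bb = bb, bp = bp, p = p,
               t_nd = t_nd)
  missing <- setdiff(info$free, names(Filter(Negate(is.null), vals)))
  if (length(missing))
    stop(sprintf("variant %s needs parameter(s): %s", info$name,
                 paste(missing, collapse = ", ")))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)")
  for (nm in intersect(c("nu", "a", "bb", "t_nd"), info$free)) {
    if (vals[[nm]] <= 0) stop(sprintf("%s must be strictly positive", nm))
  }
  out <- c(vals[info$free],
           list(z = 0.5, variant = info$name, include_nu = include_nu))
  class(out) <- "subject_params"
  out
}

#' @export
print.subject_params <- function(x, ...) {
  free <- setdiff(names(x), c("z", "variant", "include_nu"))
  cat(sprintf("<subject_params> %s (z fixed at %.1f)\n", x$variant, x$z))
  cat(paste(sprintf("  %s = %.4g", free, unlist(x[free])), collapse = "\n"),
      "\n")
  invisible(x)
}

# canonical 6-vector for the C++ core: [alpha, nu, bnd, bp, p, t_nd]
canon_vector <- function(params) {
  stopifnot(inherits(params, "subject_params"))
  canon_from_named(unlist(params[setdiff(names(params),
                                         c("z", "variant", "include_nu"))]))
}

canon_from_named <- function(v) {
  canon <- c(alpha = NA_real_, nu = 1, bnd = NA_real_, bp = 0, p = 0,
             t_nd = NA_real_)
  for (nm in names(v)) canon[CANON_SLOTS[[nm]]] <- v[[nm]]
  if (is.na(canon[1]) || is.na(canon[3]) || is.na(canon[6]))
    stop("alpha, a/bb and t_nd are required")
  unname(canon)
}

transform_to_unconstrained <- function(value, name) {
  switch(as.character(CANON_TRANS[[name]]),
         "0" = log(value / (1 - value)), "1" = log(value), value)
}

transform_to_natural <- function(value, name) {
  switch(as.character(CANON_TRANS[[name]]),
         "0" = 1 / (1 + exp(-value)), "1" = exp(value), value)
}
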