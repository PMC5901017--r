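#' Variants of the zero-inflated ordered probit family
#'
#' Tags for the six nested model variants: plain ordered probit (`OP`),
#' generalised ordered probit with covariate-dependent thresholds (`GOP`),
#' zero-inflated ordered probit without/with correlated errors
#' (`ZIOP`/`ZIOPC`), and the double-inflated model adding a misreporting
#' equation, without/with correlated errors (`DZIOP`/`DZIOPC`).
#' @export
dziop_variants <- function() c("OP", "GOP", "ZIOP", "ZIOPC", "DZIOP", "DZIOPC")

variant_has_r <- function(variant) variant %in% c("ZIOP", "ZIOPC", "DZIOP", "DZIOPC")
variant_has_m <- function(variant) variant %in% c("DZIOP", "DZIOPC")
variant_correlated <- function(variant) variant %in% c("ZIOPC", "DZIOPC")

check_variant <- function(variant) {
  if (length(variant) != 1L || !variant %in% dziop_variants())
    stop("unknown model variant: ", paste(variant, collapse = ", "),
         " (known: ", paste(dziop_variants(), collapse = ", "), ")")
  variant
}

#' Specify which covariates enter each latent equation
#'
#' Names the data columns entering the participation (`xr`), truthful
#' reporting (`xm`) and consumption (`xy`) equations, plus optional
#' threshold-equation covariates for the GOP variant.  For the
#' double-inflated variants, identification is helped by covariates that are
#' exclusive to the participation and to the misreporting equation
#' (instrument-style exclusion restrictions); a warning, not an error, is
#' issued when none are present.
#'
#' @param outcome name of the ordinal outcome column (integer codes 0..J).
#' @param xr,xm,xy character vectors of covariate column names for the
#'   participation, misreporting and consumption equations.
#' @param thresholds column names entering the GOP threshold equations.
#' @param intercept_r,intercept_m,intercept_y include an intercept (default
#'   \code{TRUE}).
#' @return an object of class `"dziop_eqspec"`.
#' @seealso [build_design()], [dziop()]
#' @export
equation_spec <- function(outcome, xr = character(), xm = character(),
                          xy = character(), thresholds = character(),
                          intercept_r = TRUE, intercept_m = TRUE,
                          intercept_y = TRUE) {
  stopifnot(is.character(outcome), length(outcome) == 1L)
  out <- list(outcome = outcome,
              xr = as.character(xr), xm = as.character(xm),
              xy = as.character(xy), thresholds = as.character(thresholds),
              intercept_r = isTRUE(intercept_r),
              intercept_m = isTRUE(intercept_m),
              intercept_y = isTRUE(intercept_y))
  class(out) <- "dziop_eqspec"
  out
}

# parse a multi-part formula y ~ xr | xm | xy (1 part: consumption only;
# 2 parts: participation | consumption; 3 parts: all equations)
split_formula_parts <- function(formula) {
  if (length(formula) != 3L)
    stop("formula must have a left-hand side (the outcome)")
  rhs <- formula[[3L]]
  parts <- list()
  while (is.call(rhs) && identical(rhs[[1L]], as.name("|"))) {
    parts <- c(list(rhs[[3L]]), parts)
    rhs <- rhs[[2L]]
  }
  parts <- c(list(rhs), parts)
  list(outcome = formula[[2L]], parts = parts)
}

part_to_columns <- function(expr) {
  f <- stats::as.formula(call("~", expr))
  tt <- stats::terms(f)
  list(columns = attr(tt, "term.labels"),
       intercept = attr(tt, "intercept") == 1L)
}

# formula -> equation_spec, given the variant
formula_to_spec <- function(formula, variant, thresholds = NULL) {
  sp <- split_formula_parts(formula)
  np <- length(sp$parts)
  need <- if (variant_has_m(variant)) 3L else if (variant_has_r(variant)) 2L else 1L
  if (np != need)
    stop(sprintf("variant %s needs %d formula part(s) (got %d): use %s",
                 variant, need, np,
                 c("y ~ xy", "y ~ xr | xy", "y ~ xr | xm | xy")[need]))
  pp <- lapply(sp$parts, part_to_columns)
  thr <- character()
  if (!is.null(thresholds)) {
    if (inherits(thresholds, "formula"))
      thr <- attr(stats::terms(thresholds), "term.labels")
    else thr <- as.character(thresholds)
  }
  if (need == 1L)
    equation_spec(deparse(sp$outcome), xy = pp[[1L]]$columns,
                  thresholds = thr, intercept_y = pp[[1L]]$intercept)
  else if (need == 2L)
    equation_spec(deparse(sp$outcome), xr = pp[[1L]]$columns,
                  xy = pp[[2L]]$columns, thresholds = thr,
                  intercept_r = pp[[1L]]$intercept,
                  intercept_y = pp[[2L]]$intercept)
  else
    equation_spec(deparse(sp$outcome), xr = pp[[1L]]$columns,
                  xm = pp[[2L]]$columns, xy = pp[[3L]]$columns,
                  thresholds = thr,
                  intercept_r = pp[[1L]]$intercept,
                  intercept_m = pp[[2L]]$intercept,
                  intercept_y = pp[[3L]]$intercept)
}

build_one_design <- function(data, columns, intercept, what, n) {
  miss <- setdiff(columns, names(data))
  if (length(miss))
    stop("column(s) missing from data for the ", what, " equation: ",
         paste(miss, collapse = ", "))
  X <- if (length(columns))
    as.matrix(as.data.frame(lapply(data[columns], as.numeric)))
  else matrix(numeric(0), nrow = n, ncol = 0)
  colnames(X) <- columns
  if (intercept) {
    X <- cbind(`(Intercept)` = rep(1, n), X)
  }
  if (ncol(X) && anyNA(X))
    stop("missing values in the ", what, " design matrix")
  X
}

#' Build the outcome vector and design matrices for estimation
#'
#' Validates the data against an [equation_spec()] and assembles the aligned
#' design matrices for the three latent equations (plus threshold covariates
#' for GOP).  The number of outcome categories J is inferred as the largest
#' observed code.
#'
#' @param data a data frame with the named columns.
#' @param spec an [equation_spec()].
#' @param variant model variant tag (used only for the exclusion-restriction
#'   warning); see [dziop_variants()].
#' @return an object of class `"dziop_obs"`: list with elements `y`, `n`,
#'   `J`, `Xr`, `Xm`, `Xy`, `Zt` and the spec.
#' @export
build_design <- function(data, spec, variant = "DZIOP") {
  stopifnot(inherits(spec, "dziop_eqspec"))
  data <- as.data.frame(data)
  if (!spec$outcome %in% names(data))
    stop("outcome column not found in data: ", spec$outcome)
  y <- data[[spec$outcome]]
  if (anyNA(y)) stop("missing values in the outcome column")
  if (!is.numeric(y) || any(y != round(y)))
    stop("outcome must be integer-coded (0, 1, ..., J); found non-integer values")
  if (any(y < 0)) stop("outcome codes must be non-negative")
  y <- as.integer(round(y))
  J <- max(y)
  if (J < 2L) stop("need at least three outcome categories (J >= 2)")
  cnt <- tabulate(y + 1L, nbins = J + 1L)
  if (any(cnt == 0L))
    warning("outcome categories with zero observations: ",
            paste(which(cnt == 0L) - 1L, collapse = ", "),
            " (estimation may be unstable)")
  n <- nrow(data)
  obs <- list(
    y = y, n = n, J = J,
    Xr = build_one_design(data, spec$xr, spec$intercept_r, "participation", n),
    Xm = build_one_design(data, spec$xm, spec$intercept_m, "misreporting", n),
    Xy = build_one_design(data, spec$xy, spec$intercept_y, "consumption", n),
    Zt = build_one_design(data, spec$thresholds, FALSE, "threshold", n),
    spec = spec)
  if (variant_has_m(variant)) {
    if (!length(setdiff(spec$xm, union(spec$xr, spec$xy))) ||
        !length(setdiff(spec$xr, union(spec$xm, spec$xy))))
      warning("no covariate exclusive to the misreporting and/or the ",
              "participation equation; identification may be fragile")
  }
  class(obs) <- "dziop_obs"
  obs
}

#' @export
print.dziop_obs <- function(x, ...) {
  cat(sprintf("dziop observation set: n = %d, categories 0..%d\n", x$n, x$J))
  cat(sprintf("  participation: %d column(s); misreporting: %d; consumption: %d; thresholds: %d\n",
              ncol(x$Xr), ncol(x$Xm), ncol(x$Xy), ncol(x$Zt)))
  frq <- table(factor(x$y, levels = 0:x$J)) / x$n
  cat("  outcome shares:", paste(sprintf("%d: %.3f", 0:x$J, frq), collapse = ", "), "\n")
  invisible(x)
}
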