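#' Design-matrix terms for the share model
#'
#' A design specification maps the fundamental pixel covariates `X` to the
#' regressor vector `W(X)` entering the multinomial logit index.  Terms are
#' kept in the order given, which fixes the column order of the design
#' matrix (and therefore the parameter layout) deterministically.
#'
#' Available terms:
#' * `term_linear(var)` — the covariate itself;
#' * `term_square(var)` — its square;
#' * `term_interaction(var_a, var_b)` — the product of two covariates;
#' * `term_hinge_below(var, pivot)` — `max(pivot - var, 0)`, the deviation
#'   below a pivot such as the agronomic optimum soil pH 6.5;
#' * `term_hinge_above(var, pivot)` — `max(var - pivot, 0)`;
#' * `term_indicator(var, base)` — one 0/1 column per level of a grouping
#'   column (e.g. country), omitting the base level.  Indicator columns are
#'   shared across crops like every other design column.
#'
#' @param var,var_a,var_b Name of a covariate column in the pixel table.
#' @param pivot Finite hinge pivot on the covariate scale.
#' @param base Level used as the reference group and omitted from the
#'   expansion.  Defaults to the first level in sorted order.
#'
#' @return An object of class `design_term`.
#' @seealso [design_spec()], [build_design()]
#' @examples
#' design_spec(term_linear("temperature"), term_square("temperature"))
#' @export
term_linear <- function(var) new_term("linear", var = chr1(var))

#' @rdname term_linear
#' @export
term_square <- function(var) new_term("square", var = chr1(var))

#' @rdname term_linear
#' @export
term_interaction <- function(var_a, var_b) {
  new_term("interaction", var = chr1(var_a), var_b = chr1(var_b))
}

#' @rdname term_linear
#' @export
term_hinge_below <- function(var, pivot) {
  stopifnot(is.numeric(pivot), length(pivot) == 1L, is.finite(pivot))
  new_term("hinge_below", var = chr1(var), pivot = pivot)
}

#' @rdname term_linear
#' @export
term_hinge_above <- function(var, pivot) {
  stopifnot(is.numeric(pivot), length(pivot) == 1L, is.finite(pivot))
  new_term("hinge_above", var = chr1(var), pivot = pivot)
}

#' @rdname term_linear
#' @export
term_indicator <- function(var, base = NULL) {
  new_term("indicator", var = chr1(var), base = base)
}

new_term <- function(type, var, var_b = NULL, pivot = NULL, base = NULL) {
  structure(
    list(type = type, var = var, var_b = var_b, pivot = pivot, base = base),
    class = "design_term"
  )
}

chr1 <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort("term variables must be single column names")
  }
  x
}

#' @export
format.design_term <- function(x, ...) {
  switch(x$type,
    linear = x$var,
    square = paste0(x$var, "^2"),
    interaction = paste0(x$var, ":", x$var_b),
    hinge_below = sprintf("below(%s,%g)", x$var, x$pivot),
    hinge_above = sprintf("above(%s,%g)", x$var, x$pivot),
    indicator = paste0("indicator(", x$var, ")")
  )
}

#' @export
print.design_term <- function(x, ...) {
  cat("<design_term>", format(x), "\n")
  invisible(x)
}

#' Create a design specification
#'
#' @param ... `design_term` objects, in the column order wanted.
#' @param intercept Include a leading column of ones?  Default `TRUE`.
#'
#' @return A `design_spec` object: an ordered term list plus the intercept
#'   flag.
#' @examples
#' spec <- design_spec(
#'   term_linear("temperature"), term_square("temperature"),
#'   term_hinge_below("ph", 6.5), term_hinge_above("ph", 6.5)
#' )
#' @export
design_spec <- function(..., intercept = TRUE) {
  terms <- list(...)
  if (length(terms) == 1L && is.list(terms[[1]]) &&
      !inherits(terms[[1]], "design_term")) {
    terms <- terms[[1]]
  }
  if (length(terms) == 0L && !isTRUE(intercept)) {
    abort("design_spec needs at least one term (or an intercept)")
  }
  ok <- vapply(terms, inherits, logical(1), what = "design_term")
  if (!all(ok)) abort("all arguments to design_spec must be design terms")
  structure(
    list(terms = terms, intercept = isTRUE(intercept)),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec> ", if (x$intercept) "1 + " else "",
      paste(vapply(x$terms, format, character(1)), collapse = " + "),
      "\n", sep = "")
  invisible(x)
}

design_vars <- function(spec) {
  unique(unlist(lapply(spec$terms, function(tm) c(tm$var, tm$var_b))))
}

#' Continuous fundamental variables of a design
#'
#' Variables entering through linear, square, interaction or hinge terms
#' (i.e. everything except grouping columns used by indicator terms).
#'
#' @param spec A [design_spec()].
#' @return Character vector of covariate names.
#' @export
design_continuous_vars <- function(spec) {
  cont <- vapply(spec$terms, function(tm) tm$type != "indicator", logical(1))
  unique(unlist(lapply(spec$terms[cont], function(tm) c(tm$var, tm$var_b))))
}

#' Build the design matrix for a pixel table
#'
#' Expands every term of `spec` against the covariate columns of `pixels`,
#' in the order the terms were given.  Indicator terms expand to one
#' column per non-base level.  The result is purely a function of its
#' inputs: identical inputs give an identical matrix.
#'
#' @param pixels A pixel table (one row per pixel) carrying every
#'   covariate named in `spec`.
#' @param spec A [design_spec()].
#'
#' @return A numeric matrix with one row per pixel and named columns;
#'   attribute `"terms"` records which term produced each column.
#' @examples
#' px <- tibble::tibble(temperature = c(10, 20), precipitation = c(2, 1))
#' build_design(px, design_spec(
#'   term_linear("temperature"),
#'   term_interaction("temperature", "precipitation")
#' ))
#' @export
build_design <- function(pixels, spec) {
  stopifnot(inherits(spec, "design_spec"), is.data.frame(pixels))
  n <- nrow(pixels)
  get_col <- function(var) {
    if (!var %in% names(pixels)) {
      abort(sprintf("design variable '%s' not found in pixel table", var),
            class = "cropdown_unknown_variable")
    }
    x <- pixels[[var]]
    if (is.numeric(x) && any(!is.finite(x))) {
      bad <- which(!is.finite(x))
      id <- if ("pixel_id" %in% names(pixels)) {
        paste(pixels$pixel_id[head(bad, 5L)], collapse = ", ")
      } else {
        paste("row", paste(head(bad, 5L), collapse = ", "))
      }
      abort(sprintf("non-finite values in covariate '%s' (pixels: %s)",
                    var, id),
            class = "cropdown_nonfinite_covariate")
    }
    x
  }

  cols <- list()
  term_of <- character(0)
  if (spec$intercept) {
    cols[["(Intercept)"]] <- rep(1, n)
    term_of <- "(Intercept)"
  }
  for (tm in spec$terms) {
    lab <- format(tm)
    if (tm$type == "indicator") {
      x <- as.character(get_col(tm$var))
      levs <- sort(unique(x))
      base <- tm$base %||% levs[1L]
      if (!base %in% levs && length(levs) > 0L) {
        abort(sprintf("indicator base level '%s' not present in '%s'",
                      base, tm$var))
      }
      for (lv in setdiff(levs, base)) {
        nm <- paste0(tm$var, "=", lv)
        cols[[nm]] <- as.numeric(x == lv)
        term_of <- c(term_of, lab)
      }
    } else {
      v <- as.numeric(get_col(tm$var))
      col <- switch(tm$type,
        linear = v,
        square = v^2,
        interaction = v * as.numeric(get_col(tm$var_b)),
        hinge_below = pmax(tm$pivot - v, 0),
        hinge_above = pmax(v - tm$pivot, 0)
      )
      cols[[lab]] <- col
      term_of <- c(term_of, lab)
    }
  }
  W <- do.call(cbind, cols)
  colnames(W) <- names(cols)
  attr(W, "terms") <- term_of
  W
}
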