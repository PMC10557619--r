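# Restricted cubic spline (natural cubic spline) basis in Harrell's
# truncated-power form with (t_k - t_1)^2 normalization. With k knots the
# basis has one linear column and k - 2 nonlinear columns; the spanned
# functions are linear beyond the boundary knots with continuous first and
# second derivatives everywhere.

#' Restricted cubic spline basis specification
#'
#' @param knots strictly increasing knot ages in years; the default
#'   `c(2, 4, 22, 35, 75, 90)` places knots at expected developmental and
#'   aging shifts across the lifespan.
#' @return an object of class `rcs_spec`.
#' @export
rcs_spec <- function(knots = c(2, 4, 22, 35, 75, 90)) {
  knots <- as.numeric(knots)
  if (length(knots) < 3) stop("need at least 3 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  structure(list(knots = knots, scale = (knots[length(knots)] - knots[1])^2),
            class = "rcs_spec")
}

#' @export
print.rcs_spec <- function(x, ...) {
  cat("<rcs_spec> knots:", paste(x$knots, collapse = ", "), "years\n")
  invisible(x)
}

#' Restricted cubic spline design columns
#'
#' Column 1 is age; nonlinear column j (j = 1..k-2) is
#' `[(a - t_j)+^3 - (a - t_{k-1})+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (a - t_k)+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2`.
#' All nonlinear columns vanish below the first knot and are linear beyond
#' the last knot.
#'
#' @param ages ages in years.
#' @param spec an [rcs_spec()].
#' @return numeric matrix with k - 1 columns (`age`, `rcs1`, ...).
#' @export
rcs_basis <- function(ages, spec = rcs_spec()) {
  t <- spec$knots
  k <- length(t)
  pos3 <- function(x) pmax(x, 0)^3
  X <- matrix(0, length(ages), k - 1)
  X[, 1] <- ages
  for (j in seq_len(k - 2)) {
    X[, j + 1] <- (pos3(ages - t[j]) -
                     pos3(ages - t[k - 1]) * (t[k] - t[j]) / (t[k] - t[k - 1]) +
                     pos3(ages - t[k]) * (t[k - 1] - t[j]) / (t[k] - t[k - 1])) /
      spec$scale
  }
  colnames(X) <- c("age", paste0("rcs", seq_len(k - 2)))
  X
}

#' Analytic derivative of the RCS design columns with respect to age
#'
#' @param ages ages in years.
#' @param spec an [rcs_spec()].
#' @return matrix matching [rcs_basis()] columns, holding d/d age.
#' @export
rcs_basis_deriv <- function(ages, spec = rcs_spec()) {
  t <- spec$knots
  k <- length(t)
  pos2 <- function(x) pmax(x, 0)^2
  D <- matrix(0, length(ages), k - 1)
  D[, 1] <- 1
  for (j in seq_len(k - 2)) {
    D[, j + 1] <- 3 * (pos2(ages - t[j]) -
                         pos2(ages - t[k - 1]) * (t[k] - t[j]) / (t[k] - t[k - 1]) +
                         pos2(ages - t[k]) * (t[k - 1] - t[j]) / (t[k] - t[k - 1])) /
      spec$scale
  }
  colnames(D) <- c("age", paste0("rcs", seq_len(k - 2)))
  D
}
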