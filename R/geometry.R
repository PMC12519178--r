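# Circle-fitting model: edge averaging, Ramanujan ellipse circumference,
# equivalent circular diameter. All lengths in millimetres.

#' Average a pair of edge measurements
#'
#' Each diameter (maximum or minimum, pre- or post-placement) is measured at
#' the superior (`x1`) and inferior (`x2`) margins of the region of interest
#' and reported as their arithmetic mean.
#'
#' @param x1 Numeric vector, diameter at the superior margin (mm).
#' @param x2 Numeric vector, diameter at the inferior margin (mm).
#' @return Numeric vector of mean diameters (mm).
#' @examples
#' mean_edge_diameter(10, 12)  # 11
#' @export
mean_edge_diameter <- function(x1, x2) {
  check_positive_finite(x1, "x1")
  check_positive_finite(x2, "x2")
  (x1 + x2) / 2
}

#' Ramanujan approximation of an ellipse circumference
#'
#' First Ramanujan approximation
#' \deqn{C \approx \pi\left[3(a+b) - \sqrt{(3a+b)(a+3b)}\right]}
#' which is exact for circles (`a == b`) and has relative error below 0.5%
#' over the full range of aspect ratios (below 1e-4 for `b/a >= 0.3`).
#'
#' @param a Semi-major axis (mm), `a >= b`.
#' @param b Semi-minor axis (mm), `b > 0`.
#' @return Approximated circumference (mm). Vectorized over `a`, `b`.
#' @examples
#' ramanujan_circumference(1, 1)  # 2 * pi
#' @export
ramanujan_circumference <- function(a, b) {
  check_positive_finite(a, "a")
  check_positive_finite(b, "b")
  if (any(a < b)) {
    stop("semi-major axis 'a' must be >= semi-minor axis 'b' (offending index ",
         which(a < b)[1L], ")", call. = FALSE)
  }
  out <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  circle <- a == b  # exact circle case, bypassing radical rounding
  out[circle] <- 2 * pi * a[circle]
  out
}

#' Equivalent circular diameter from a circumference
#'
#' Diameter of the circle whose circumference equals `circumference`.
#'
#' @param circumference Circumference (mm), positive.
#' @return Diameter (mm).
#' @export
equivalent_diameter <- function(circumference) {
  check_positive_finite(circumference, "circumference")
  circumference / pi
}

#' Predict the post-placement IVC diameter from pre-placement diameters
#'
#' The oval pre-placement cross-section with maximum diameter `d_max` and
#' minimum diameter `d_min` is modelled as an ellipse with semi-axes
#' `a = d_max/2`, `b = d_min/2`; its circumference is approximated with
#' [ramanujan_circumference()] and converted to the equivalent circular
#' diameter, which in closed form is
#' \deqn{D_{eq} = 1.5\,(D_{max}+D_{min}) -
#'   \sqrt{(1.5 D_{max} + 0.5 D_{min})(0.5 D_{max} + 1.5 D_{min})}.}
#' Since the vessel tends to a near-circular cross-section after filter
#' placement while (to first order) conserving its perimeter, `d_eq` predicts
#' both the post-placement maximum and minimum diameters.
#'
#' @param d_max Maximum pre-placement diameter (mm).
#' @param d_min Minimum pre-placement diameter (mm); must not exceed `d_max`
#'   unless `auto_sort = TRUE`.
#' @param auto_sort If `TRUE`, rows with `d_max < d_min` are swapped with a
#'   warning instead of failing (tolerates unordered single-angle files).
#' @return A data frame of class `ivc_prediction` with columns `d_max`,
#'   `d_min`, `a`, `b`, `circumference`, `d_eq` (all mm).
#' @examples
#' predict_equivalent_diameter(15.52, 8.88)
#' @export
predict_equivalent_diameter <- function(d_max, d_min, auto_sort = FALSE) {
  check_positive_finite(d_max, "d_max")
  check_positive_finite(d_min, "d_min")
  if (length(d_max) != length(d_min)) {
    stop("'d_max' and 'd_min' must have the same length", call. = FALSE)
  }
  swapped <- d_max < d_min
  if (any(swapped)) {
    if (!auto_sort) {
      stop("d_max < d_min at index ", which(swapped)[1L],
           "; fix the input or set auto_sort = TRUE", call. = FALSE)
    }
    warning(sum(swapped), " row(s) had d_max < d_min and were swapped",
            call. = FALSE)
    tmp <- d_max[swapped]
    d_max[swapped] <- d_min[swapped]
    d_min[swapped] <- tmp
  }
  a <- d_max / 2
  b <- d_min / 2
  circ <- ramanujan_circumference(a, b)
  d_eq <- circ / pi
  circle <- d_max == d_min  # a circular cross-section is its own prediction
  d_eq[circle] <- d_max[circle]
  res <- data.frame(
    d_max = d_max, d_min = d_min, a = a, b = b,
    circumference = circ, d_eq = d_eq
  )
  class(res) <- c("ivc_prediction", "data.frame")
  res
}

#' @export
print.ivc_prediction <- function(x, digits = 2, ...) {
  cat("Circle-fitting equivalent-diameter prediction (mm)\n")
  y <- as.data.frame(lapply(x, round, digits = digits))
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}

# shared validator: positive, finite, numeric
check_positive_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("'", name, "' must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop("'", name, "' must be positive and finite (offending index ",
         which(bad)[1L], ": ", x[which(bad)[1L]], ")", call. = FALSE)
  }
  invisible(x)
}
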