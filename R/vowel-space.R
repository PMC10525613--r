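# Triangular vowel space area.

#' Triangular vowel space area (tVSA)
#'
#' Area of the triangle spanned by the (F1, F2) coordinates of the corner
#' vowels /a/, /i/, /u/:
#' \deqn{tVSA = |F1_i (F2_a - F2_u) + F1_a (F2_u - F2_i) +
#'               F1_u (F2_i - F2_a)| / 2}
#' in Hz squared.  The absolute value makes the area orientation-independent;
#' collinear vertices give area 0.  Formant centralization (dysarthria)
#' compresses the area: shrinking all formant deviations from the centroid
#' by a factor \eqn{c} scales the area by \eqn{c^2}.
#'
#' @param fa,fi,fu \code{\link{vowel_targets}} results (or lists with
#'   \code{F1}, \code{F2} fields) for /a/, /i/ and /u/.  When vowel labels
#'   are present they must be distinct.
#' @return A \code{tvsa_result}: list with \code{area} (Hz^2) and
#'   \code{vertices} (3 x 2 matrix, rows a/i/u, columns F1/F2).
#' @examples
#' tvsa(fa = list(F1 = 800, F2 = 1300),
#'      fi = list(F1 = 300, F2 = 2300),
#'      fu = list(F1 = 350, F2 = 800))  # 350000 Hz^2
#' @export
tvsa <- function(fa, fi, fu) {
  pts <- list(a = fa, i = fi, u = fu)
  labs <- vapply(pts, function(p) as.character(p$vowel %||% NA_character_),
                 character(1))
  if (anyDuplicated(labs[!is.na(labs)]))
    stop("duplicate vowel labels supplied to tvsa()")
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.finite(p$F1) || !is.finite(p$F2))
      stop(sprintf("non-finite formants for /%s/", nm))
  }
  v <- rbind(a = c(fa$F1, fa$F2), i = c(fi$F1, fi$F2), u = c(fu$F1, fu$F2))
  colnames(v) <- c("F1", "F2")
  area <- abs(v["i", 1] * (v["a", 2] - v["u", 2]) +
              v["a", 1] * (v["u", 2] - v["i", 2]) +
              v["u", 1] * (v["i", 2] - v["a", 2])) / 2
  structure(list(area = area, vertices = v), class = "tvsa_result")
}

#' @export
print.tvsa_result <- function(x, ...) {
  cat(sprintf("<tvsa_result: %.0f Hz^2>\n", x$area))
  invisible(x)
}
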