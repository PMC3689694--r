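#' Fold-change thresholds for translational calls
#'
#' The study design calls a ratio "up" when it reaches `up` (default 1.5)
#' and "down" when it falls to `down` (default 0.67). With
#' `inclusive = TRUE` (default) the boundary values themselves count as
#' modified, i.e. calls use `>=` / `<=`; with `inclusive = FALSE` the
#' comparison is strict. The unmodified band is always the open interval
#' `(down, up)` under the inclusive convention.
#'
#' @param up upper fold-change threshold, must be > 1.
#' @param down lower fold-change threshold, must lie in (0, 1).
#' @param inclusive logical; should boundary values count as modified?
#' @return an object of class `rr_thresholds`.
#' @examples
#' th <- thresholds()
#' th$up
#' @export
thresholds <- function(up = 1.5, down = 0.67, inclusive = TRUE) {
  stopifnot(is.numeric(up), length(up) == 1L, is.finite(up),
            is.numeric(down), length(down) == 1L, is.finite(down),
            is.logical(inclusive), length(inclusive) == 1L)
  if (!(down < 1 && 1 < up)) {
    stop("thresholds must satisfy down < 1 < up (got down = ", down,
         ", up = ", up, ")")
  }
  structure(list(up = up, down = down, inclusive = inclusive),
            class = "rr_thresholds")
}

#' @export
print.rr_thresholds <- function(x, ...) {
  cat(sprintf("fold-change thresholds: up %s %.3g, down %s %.3g\n",
              if (x$inclusive) ">=" else ">", x$up,
              if (x$inclusive) "<=" else "<", x$down))
  invisible(x)
}

# direction of a fold change under thresholds: "up", "down" or "none"
ratio_direction <- function(x, th) {
  up <- if (th$inclusive) x >= th$up else x > th$up
  down <- if (th$inclusive) x <= th$down else x < th$down
  ifelse(up, "up", ifelse(down, "down", "none"))
}

# is an RR value beyond the modified threshold?
rr_is_modified <- function(rr, th) {
  if (th$inclusive) rr >= th$up | rr <= th$down else rr > th$up | rr < th$down
}
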