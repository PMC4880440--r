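#' Task geometry: the 3 x 3 x 3 target lattice
#'
#' Builds the lattice of 27 hand-position targets used in the posture task.
#' Targets sit on a regular 3-level grid along each Cartesian axis, centred
#' on the workspace origin, so the distance between the two farthest targets
#' (the cube diagonal) is \code{spacing * 2 * sqrt(3)}.  The task geometry
#' has a 12.1 cm diagonal, i.e. \code{spacing = 12.1 / (2 * sqrt(3))}
#' (about 3.493 cm), which is the default.
#'
#' @param spacing Distance (cm) between adjacent targets along one axis.
#' @return An object of class \code{"posture_grid"}: a list with
#'   \item{positions}{27 x 3 matrix of target coordinates (cm), target index
#'     \code{0:26} in row order \code{expand.grid} over (x, y, z) levels;}
#'   \item{spacing, d_min}{the lattice constant (cm); \code{d_min == spacing};}
#'   \item{diagonal}{distance between the two farthest targets (cm);}
#'   \item{neighbor_pairs}{54 x 2 matrix of 1-based row indices of all
#'     unordered axis-aligned nearest-neighbour pairs at distance
#'     \code{d_min}.}
#' @examples
#' g <- make_target_grid()
#' g$diagonal             # 12.1
#' nrow(g$neighbor_pairs) # 54
#' @export
make_target_grid <- function(spacing = 12.1 / (2 * sqrt(3))) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("'spacing' must be a single positive number")
  lv <- c(-spacing, 0, spacing)
  pos <- as.matrix(expand.grid(x = lv, y = lv, z = lv))
  rownames(pos) <- NULL
  pr <- t(utils::combn(27L, 2L))
  d2 <- rowSums((pos[pr[, 1L], , drop = FALSE] -
                 pos[pr[, 2L], , drop = FALSE])^2)
  nb <- pr[abs(sqrt(d2) - spacing) < 1e-9 * spacing, , drop = FALSE]
  structure(list(
    positions      = pos,
    spacing        = spacing,
    d_min          = spacing,
    diagonal       = spacing * 2 * sqrt(3),
    neighbor_pairs = nb
  ), class = "posture_grid")
}

#' @export
print.posture_grid <- function(x, ...) {
  cat("3 x 3 x 3 posture target grid\n")
  cat(sprintf("  spacing (D_min): %.4f cm,  diagonal: %.4f cm\n",
              x$spacing, x$diagonal))
  cat(sprintf("  %d targets, %d nearest-neighbour pairs\n",
              nrow(x$positions), nrow(x$neighbor_pairs)))
  invisible(x)
}

#' Condition indexing for the 54 arm postures
#'
#' The 54 task conditions are the 27 targets crossed with the two forearm
#' rotation angles.  The package fixes the ordering as target-major with
#' pronation first: condition \code{2 * target_index + 1} is
#' (target, pronation) and \code{2 * target_index + 2} is
#' (target, supination), for \code{target_index} in \code{0:26}.
#'
#' @return A 54-row data frame with columns \code{condition} (1..54),
#'   \code{target_index} (0..26) and \code{forearm_angle}
#'   (\code{"pronation"} / \code{"supination"}).
#' @export
condition_table <- function() {
  data.frame(
    condition     = 1:54,
    target_index  = rep(0:26, each = 2L),
    forearm_angle = rep(c("pronation", "supination"), 27L),
    stringsAsFactors = FALSE
  )
}

#' @rdname condition_table
#' @param target_index Integer vector in 0..26.
#' @param forearm_angle Character vector, \code{"pronation"} or
#'   \code{"supination"} (unambiguous abbreviations allowed).
#' @export
condition_index <- function(target_index, forearm_angle) {
  target_index <- as.integer(target_index)
  if (any(is.na(target_index)) || any(target_index < 0L | target_index > 26L))
    stop("'target_index' must be in 0..26")
  ang <- match.arg(forearm_angle, c("pronation", "supination"),
                   several.ok = TRUE)
  ang <- rep_len(ang, length(target_index))
  2L * target_index + ifelse(ang == "supination", 2L, 1L)
}

#' @rdname condition_table
#' @details \code{angle_columns} returns the 27 condition indices of one
#'   forearm angle, in target order 0..26 — the standard way to slice a
#'   54-condition response into its per-angle halves.
#' @export
angle_columns <- function(forearm_angle = c("pronation", "supination")) {
  forearm_angle <- match.arg(forearm_angle)
  condition_index(0:26, forearm_angle)
}
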