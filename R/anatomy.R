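# Anatomical context for the cross-region generation matrices: relative-angle
# scores between the 16 hemisphere-by-angle cortical groups, and structural
# connection strength between recording windows weighted by the fraction of
# each atlas area they cover.

group_position <- function(angular_group) {
  pos <- match(angular_group, angular_groups())
  if (anyNA(pos)) {
    abort(paste0("unknown angular group; must be one of: ",
                 paste(angular_groups(), collapse = ", ")))
  }
  pos - 1L
}

#' Relative-angle score between two region groups
#'
#' The eight angular groups per hemisphere sit 45 degrees apart on a ring.
#' The score between two groups of the same hemisphere is the circular
#' distance in 45-degree steps (0 for the same group, +1 per step), except
#' that diametrically opposite groups score 2 rather than 4 because they lie
#' on the same slice surface and are physically adjacent. Scores are only
#' defined within a hemisphere; mixing hemispheres is an error.
#'
#' @param a,b [region_label()]s (or lists with `hemisphere` and
#'   `angular_group`).
#' @return integer score in `{0, 1, 2, 3}`.
#' @export
relative_angle_score <- function(a, b) {
  a <- validate_region_label(a)
  b <- validate_region_label(b)
  if (a$hemisphere != b$hemisphere) {
    abort("relative angles are only defined within one hemisphere.")
  }
  d <- abs(group_position(a$angular_group) - group_position(b$angular_group))
  d <- min(d, 8L - d)
  if (d == 4L) 2L else as.integer(d)
}

#' All pairwise relative-angle scores
#'
#' @param hemisphere `"L"` or `"R"` (the table is identical for both).
#' @return tibble with `group_a`, `group_b`, `score` over all 64 ordered
#'   pairs of angular groups.
#' @export
angle_score_table <- function(hemisphere = "L") {
  groups <- angular_groups()
  grid <- expand.grid(group_a = groups, group_b = groups,
                      stringsAsFactors = FALSE)
  grid$score <- purrr::map2_int(grid$group_a, grid$group_b, function(ga, gb) {
    relative_angle_score(region_label(hemisphere, ga),
                         region_label(hemisphere, gb))
  })
  as_tibble(grid)
}

rect_intersection_area <- function(ax1, ax2, ay1, ay2, bx1, bx2, by1, by2) {
  pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1)) *
    pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
}

#' Atlas areas overlapped by a recording window
#'
#' Enumerates the atlas areas intersecting an axis-aligned rectangular
#' recording window and returns, per area, the intersected area `s`, the
#' area's total size `S`, and the covered fraction `R = s / S` used to
#' weight structural connections. Areas the window does not touch are
#' dropped.
#'
#' @param window rectangle: named numeric vector or list with `xmin`,
#'   `xmax`, `ymin`, `ymax` (a one-row tibble, e.g. a row of
#'   `atlas$windows`, also works).
#' @param atlas an [make_atlas_fixture()] (or [read_atlas()]) object.
#' @return tibble of class `atlas_overlap` columns: `area_id`, `s`, `S`,
#'   `R`. Zero rows (with a warning) if the window lies outside the atlas.
#' @export
window_overlaps <- function(window, atlas) {
  w <- as.list(window)[c("xmin", "xmax", "ymin", "ymax")]
  if (any(lengths(w) != 1) || anyNA(unlist(w))) {
    abort("`window` must provide scalar xmin, xmax, ymin, ymax.")
  }
  if (w$xmax <= w$xmin || w$ymax <= w$ymin) {
    abort("recording window has zero or negative area.")
  }
  a <- atlas$areas
  s <- rect_intersection_area(a$xmin, a$xmax, a$ymin, a$ymax,
                              w$xmin, w$xmax, w$ymin, w$ymax)
  S <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  if (any(S <= 0)) abort("atlas contains an area with non-positive size.")
  keep <- s > 0
  if (!any(keep)) {
    warn("recording window does not intersect any atlas area.")
  }
  frac <- s[keep] / S[keep]
  out <- tibble(area_id = a$area_id[keep], s = s[keep], S = S[keep],
                R = frac)
  class(out) <- c("atlas_overlap", class(out))
  out
}

#' Structural connection strength between two recording windows
#'
#' Area-fraction-weighted sum of atlas inter-area connection weights:
#' `sum_ij W[a_i, b_j] * R_ai * R_bj`, where `R` is the fraction of each
#' atlas area covered by the window ([window_overlaps()]). With
#' `normalize = TRUE` the sum is divided by `sum_ij R_ai * R_bj`, an
#' averaged rather than summed reading.
#'
#' @param overlap_a,overlap_b [window_overlaps()] tibbles (or precomputed
#'   tables with columns `area_id` and `R`).
#' @param W inter-area weight matrix with area ids as dimnames
#'   (rows index the first window's areas as sources).
#' @param normalize divide by the total `R_ai * R_bj` mass (default FALSE).
#' @return a single non-negative number.
#' @export
connection_strength <- function(overlap_a, overlap_b, W, normalize = FALSE) {
  for (ov in list(overlap_a, overlap_b)) {
    if (!all(c("area_id", "R") %in% names(ov))) {
      abort("overlaps need columns `area_id` and `R`.")
    }
  }
  if (nrow(overlap_a) == 0 || nrow(overlap_b) == 0) return(0)
  miss <- setdiff(c(overlap_a$area_id, overlap_b$area_id), rownames(W))
  if (length(miss) > 0) {
    abort(paste0("areas missing from the weight matrix: ",
                 paste(miss, collapse = ", ")))
  }
  sub <- W[overlap_a$area_id, overlap_b$area_id, drop = FALSE]
  mass <- outer(overlap_a$R, overlap_b$R)
  val <- sum(sub * mass)
  if (normalize) {
    tot <- sum(mass)
    if (tot <= 0) return(0)
    val <- val / tot
  }
  val
}

#' Angle scores and connection strengths for all window pairs of an atlas
#'
#' Convenience wrapper producing, for every ordered pair of recording
#' windows in a fixture, the relative-angle score (NA across hemispheres,
#' where the score is undefined) and the structural connection strength.
#'
#' @param atlas an [make_atlas_fixture()] object.
#' @param normalize passed to [connection_strength()].
#' @return tibble: `window_a`, `window_b`, `hemisphere_a`, `hemisphere_b`,
#'   `angle_score`, `strength`.
#' @export
anatomy_pairs <- function(atlas, normalize = FALSE) {
  win <- atlas$windows
  overlaps <- purrr::map(seq_len(nrow(win)),
                         function(i) window_overlaps(win[i, ], atlas))
  grid <- expand.grid(a = seq_len(nrow(win)), b = seq_len(nrow(win)))
  purrr::pmap_dfr(grid, function(a, b) {
    same_hemi <- win$hemisphere[a] == win$hemisphere[b]
    tibble(
      window_a = win$window_id[a],
      window_b = win$window_id[b],
      hemisphere_a = win$hemisphere[a],
      hemisphere_b = win$hemisphere[b],
      angle_score = if (same_hemi) {
        relative_angle_score(
          region_label(win$hemisphere[a], win$angular_group[a],
                       win$dataset_id[a]),
          region_label(win$hemisphere[b], win$angular_group[b],
                       win$dataset_id[b]))
      } else NA_integer_,
      strength = connection_strength(overlaps[[a]], overlaps[[b]], atlas$W,
                                     normalize = normalize)
    )
  })
}
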