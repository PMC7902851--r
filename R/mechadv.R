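#' Mechanical advantage of a jaw lever
#'
#' Ratio of the muscle in-lever (moment arm of the adductor about the jaw
#' joint) to the out-lever (distance from the joint to the bite point).
#' High values indicate a jaw optimized for bite force, low values for
#' closure speed.
#'
#' @param inlever,outlever positive lengths in any common unit.
#' @return `inlever / outlever` (dimensionless).
#' @export
mechanical_advantage <- function(inlever, outlever) {
  if (any(inlever <= 0) || any(outlever <= 0))
    stop("lever lengths must be positive")
  inlever / outlever
}

#' Validate a moment-arm table
#'
#' Columns: `taxon_id`, `inlever_masseter`, `inlever_temporalis`,
#' `outlever_tip` (condyle to anterior end of the jaw), `outlever_m1`
#' (condyle to first lower molar). The tip is anterior to m1, so
#' `outlever_tip >= outlever_m1`.
#'
#' @param arms data frame of moment arms.
#' @return `arms`, invisibly, after checks.
#' @export
validate_moment_arms <- function(arms) {
  req <- c("taxon_id", "inlever_masseter", "inlever_temporalis",
           "outlever_tip", "outlever_m1")
  miss <- setdiff(req, names(arms))
  if (length(miss)) stop("moment-arm table missing: ", paste(miss, collapse = ", "))
  num <- as.matrix(arms[, req[-1]])
  bad <- arms$taxon_id[apply(num, 1L, function(r) any(!is.finite(r) | r <= 0))]
  if (length(bad)) stop("non-positive moment arm for: ", paste(bad, collapse = ", "))
  bad <- arms$taxon_id[arms$outlever_tip < arms$outlever_m1]
  if (length(bad)) stop("outlever_tip < outlever_m1 for: ", paste(bad, collapse = ", "))
  invisible(arms)
}

#' Mechanical-advantage table
#'
#' Computes the four ratios per taxon: masseter and temporalis mechanical
#' advantage with the out-lever at the jaw tip (`MAM_tip`, `MAT_tip`) and at
#' the first lower molar (`MAM_m1`, `MAT_m1`). Because the m1 out-lever is
#' shorter, `MA_m1 > MA_tip` for the same muscle, and
#' `MA_m1 / MA_tip = outlever_tip / outlever_m1` exactly for both muscles.
#'
#' @param arms moment-arm data frame (see [validate_moment_arms()]).
#' @return data frame with `taxon_id` and the four MA columns.
#' @export
ma_table <- function(arms) {
  validate_moment_arms(arms)
  data.frame(
    taxon_id = arms$taxon_id,
    MAM_tip = mechanical_advantage(arms$inlever_masseter, arms$outlever_tip),
    MAT_tip = mechanical_advantage(arms$inlever_temporalis, arms$outlever_tip),
    MAM_m1  = mechanical_advantage(arms$inlever_masseter, arms$outlever_m1),
    MAT_m1  = mechanical_advantage(arms$inlever_temporalis, arms$outlever_m1),
    stringsAsFactors = FALSE)
}

#' Moment arms from designated landmarks
#'
#' Straight-line distances from the condyle (the pitch axis of rotation,
#' assumed at the jaw joint in all taxa) to the user-designated masseter
#' attachment (angular region), temporalis attachment (coronoid apex),
#' anterior jaw tip and m1 position. The attachment loci are configurable so
#' other moment-arm conventions can be expressed.
#'
#' @param config a [landmark_config()].
#' @param point_map named list/vector with landmark indices `condyle`,
#'   `masseter`, `temporalis`, `tip`, `m1`.
#' @return one-row moment-arm data frame.
#' @export
arms_from_landmarks <- function(config, point_map) {
  req <- c("condyle", "masseter", "temporalis", "tip", "m1")
  miss <- setdiff(req, names(point_map))
  if (length(miss)) stop("point_map missing: ", paste(miss, collapse = ", "))
  idx <- unlist(point_map[req])
  if (any(idx < 1L | idx > nrow(config$coords)))
    stop("point_map index out of range for '", config$taxon_id, "'")
  p <- config$coords[idx, , drop = FALSE]
  d <- sqrt(rowSums(sweep(p[-1, , drop = FALSE], 2L, p[1, ])^2))
  arms <- data.frame(
    taxon_id = config$taxon_id,
    inlever_masseter = d[1], inlever_temporalis = d[2],
    outlever_tip = d[3], outlever_m1 = d[4],
    stringsAsFactors = FALSE)
  validate_moment_arms(arms)
  arms
}
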