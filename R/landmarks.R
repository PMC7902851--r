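#' Landmark configuration
#'
#' A single taxon's 2D landmark set with fixed/sliding semantics. The default
#' regimen used throughout this package mirrors a common mandible scheme:
#' a small number of fixed anatomical landmarks (condyle, coronoid apex,
#' angular region, anterior tip, ...) joined by curves of sliding
#' semi-landmarks along the jaw outline.
#'
#' @param taxon_id single character id.
#' @param coords k x 2 numeric matrix of (x, y) coordinates in image units.
#' @param fixed_idx integer vector of fixed-landmark indices (1-based).
#' @param curves list of integer vectors; each vector is an ordered chain of
#'   landmark indices whose first and last elements are the chain's anchors
#'   (normally fixed landmarks) and whose interior elements are sliding
#'   semi-landmarks.
#' @param scale optional physical units per image unit (from a TPS `SCALE=`
#'   record); not applied unless requested explicitly.
#'
#' @return an object of class `landmark_config`.
#' @export
landmark_config <- function(taxon_id, coords, fixed_idx, curves = list(),
                            scale = NA_real_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must be a k x 2 matrix")
  if (nrow(coords) > 0L && !all(is.finite(coords)))
    stop("non-finite coordinate in configuration '", taxon_id, "'")
  fixed_idx <- as.integer(fixed_idx)
  curves <- lapply(curves, as.integer)
  k <- nrow(coords)
  sliding <- sliding_indices(curves)
  claimed <- c(fixed_idx, unlist(lapply(curves, function(ch) ch[-c(1L, length(ch))])))
  if (k > 0L) {
    if (anyDuplicated(claimed))
      stop("landmark index assigned to more than one role in '", taxon_id, "'")
    if (length(claimed) != k || !setequal(claimed, seq_len(k)))
      stop("fixed_idx + curve interiors must partition 1..k in '", taxon_id, "'")
    for (ch in curves) {
      if (length(ch) < 3L)
        stop("curve with no sliding interior in '", taxon_id, "'")
      if (any(ch < 1L | ch > k))
        stop("curve index out of range in '", taxon_id, "'")
    }
  }
  structure(
    list(taxon_id = as.character(taxon_id), coords = coords,
         fixed_idx = fixed_idx, curves = curves,
         sliding_idx = sliding, scale = scale),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s: %d landmarks (%d fixed, %d sliding)\n",
              x$taxon_id, nrow(x$coords), length(x$fixed_idx),
              length(x$sliding_idx)))
  invisible(x)
}

sliding_indices <- function(curves) {
  as.integer(unlist(lapply(curves, function(ch) ch[-c(1L, length(ch))])))
}

#' Neighbour map for sliding semi-landmarks
#'
#' For each sliding semi-landmark, the previous/next landmark along its chain
#' (anchors allowed as neighbours). Used to define the tangent direction
#' during sliding.
#'
#' @param config a `landmark_config`.
#' @return integer matrix with columns `idx`, `prev`, `nxt`, one row per
#'   sliding semi-landmark.
#' @keywords internal
slider_neighbours <- function(config) {
  rows <- lapply(config$curves, function(ch) {
    n <- length(ch)
    cbind(idx = ch[2:(n - 1L)], prev = ch[1:(n - 2L)], nxt = ch[3:n])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("idx", "prev", "nxt")))
  out
}

#' Read a TPS landmark file
#'
#' Parses the Rohlf TPS dialect: `LM=` records followed by coordinate lines,
#' with optional `IMAGE=`, `ID=` and `SCALE=` lines per record. `CURVES=` /
#' `POINTS=` records are tolerated but ignored: fixed/sliding semantics come
#' from a sidecar descriptor (see [read_slider_descriptor()]), since TPS
#' itself does not encode them. Integer and decimal coordinates, trailing
#' whitespace and Windows line endings are all accepted.
#'
#' @param path TPS file path.
#' @param curves optional list of sliding chains applied to every
#'   configuration (as in [landmark_config()]); when `NULL` all landmarks are
#'   treated as fixed.
#' @param apply_scale multiply coordinates by the record's `SCALE=` factor
#'   when present. Never applied silently: the default is `FALSE`.
#' @return list of `landmark_config`, in record order.
#' @export
read_tps <- function(path, curves = NULL, apply_scale = FALSE) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  configs <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("line ", i, ": expected an LM= record, got '", ln, "'")
    rec <- rec + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 0L) stop("record ", rec, ": malformed LM= count")
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > length(lines))
        stop("record ", rec, ": file ends before ", k, " coordinate lines")
      fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) != 2L || any(is.na(vals))) {
        if (grepl("=", lines[i]))
          stop("record ", rec, ": only ", j - 1L,
               " coordinate lines found, LM= said ", k)
        stop("line ", i, ": non-numeric coordinate '", lines[i], "'")
      }
      coords[j, ] <- vals
      i <- i + 1L
    }
    id <- sprintf("record_%d", rec)
    scale <- NA_real_
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln, ignore.case = TRUE))
      } else if (grepl("^(IMAGE|CURVES|POINTS)\\s*=", ln, ignore.case = TRUE)) {
        # tolerated, not used
      } else break
      i <- i + 1L
    }
    if (apply_scale && !is.na(scale)) coords <- coords * scale
    cfg_curves <- if (is.null(curves) || k == 0L) list() else curves
    fixed <- if (k == 0L) integer(0) else
      setdiff(seq_len(k), sliding_indices(cfg_curves))
    configs[[rec]] <- landmark_config(id, coords, fixed, cfg_curves,
                                      scale = scale)
  }
  configs
}

#' Write configurations to a TPS file (with sidecar descriptor)
#'
#' Emits one `LM=`/`ID=` record per configuration, readable by [read_tps()].
#' Fixed/sliding semantics are stored in a JSON-free plain-text sidecar
#' (`<path>.sliders`) listing each curve as a whitespace-separated index
#' chain, because the TPS format does not encode them.
#'
#' @param configs list of `landmark_config`.
#' @param path output file path.
#' @param sidecar write the slider descriptor next to `path`.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path, sidecar = TRUE) {
  if (length(configs) == 0L) {
    warning("writing an empty TPS file: no configurations supplied")
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM=%d", nrow(cf$coords)),
      apply(cf$coords, 1L, function(p)
        sprintf("%.10f %.10f", p[1], p[2])),
      sprintf("ID=%s", cf$taxon_id),
      if (!is.na(cf$scale)) sprintf("SCALE=%.10f", cf$scale))
  }))
  writeLines(out, path)
  if (sidecar)
    write_slider_descriptor(configs[[1]]$curves, paste0(path, ".sliders"))
  invisible(path)
}

#' @rdname write_tps
#' @param curves list of integer chains to store.
#' @export
write_slider_descriptor <- function(curves, path) {
  writeLines(vapply(curves, function(ch) paste(ch, collapse = " "), ""), path)
  invisible(path)
}

#' @rdname read_tps
#' @export
read_slider_descriptor <- function(path) {
  lines <- trimws(sub("\r$", "", readLines(path, warn = FALSE)))
  lines <- lines[lines != ""]
  lapply(lines, function(ln) as.integer(strsplit(ln, "\\s+")[[1]]))
}

#' Read the per-taxon attribute table
#'
#' CSV with required columns `taxon_id`, `diet_class`
#' (insectivore/carnivore/herbivore/omnivore/unknown) and `role`
#' (training/predict); any further columns (moment-arm lengths, display
#' numbers, appearance dates) are carried through typed as read.
#'
#' @param path CSV path.
#' @return data frame, one row per taxon.
#' @export
read_taxon_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("taxon_id", "diet_class", "role")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("taxon table missing columns: ",
                         paste(miss, collapse = ", "))
  dup <- tab$taxon_id[duplicated(tab$taxon_id)]
  if (length(dup)) stop("duplicate taxon_id: ", paste(unique(dup), collapse = ", "))
  diets <- c("insectivore", "carnivore", "herbivore", "omnivore", "unknown")
  bad <- setdiff(unique(tab$diet_class), diets)
  if (length(bad)) stop("unknown diet_class value(s): ", paste(bad, collapse = ", "))
  if (!all(tab$role %in% c("training", "predict")))
    stop("role must be 'training' or 'predict'")
  offenders <- tab$taxon_id[tab$role == "training" & tab$diet_class == "unknown"]
  if (length(offenders))
    stop("training taxa with unknown diet: ", paste(offenders, collapse = ", "))
  tab
}

#' Read a cladogram plus tip appearance dates
#'
#' @param tree_path Newick file; branch lengths, if present, are ignored
#'   (the topology is the input to time-scaling).
#' @param ages_path optional CSV with columns `taxon_id`, `fad` (first
#'   appearance, Ma) and optionally `lad`. Tips absent from the table default
#'   to age 0 only when the table is omitted entirely; with a table, every
#'   fossil tip must be listed (extant tips may be omitted and default to 0).
#' @param constraints_path optional CSV with columns `mrca_of` (a
#'   semicolon-separated pair of tip names identifying a node) and `min_age`.
#' @return list with `tree` (ape `phylo`), `tip_ages` (named numeric, FADs),
#'   `lads` (named numeric), `constraints` (data frame or NULL).
#' @export
read_newick_with_ages <- function(tree_path, ages_path = NULL,
                                  constraints_path = NULL) {
  tree <- ape::read.tree(tree_path)
  tip_ages <- stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label)
  lads <- tip_ages
  if (!is.null(ages_path)) {
    ages <- utils::read.csv(ages_path, stringsAsFactors = FALSE)
    if (!all(c("taxon_id", "fad") %in% names(ages)))
      stop("ages table needs columns taxon_id, fad")
    unmatched <- setdiff(ages$taxon_id, tree$tip.label)
    if (length(unmatched))
      stop("age table rows not on the tree: ", paste(unmatched, collapse = ", "))
    tip_ages[ages$taxon_id] <- ages$fad
    if ("lad" %in% names(ages)) lads[ages$taxon_id] <- ages$lad
  }
  constraints <- NULL
  if (!is.null(constraints_path)) {
    constraints <- utils::read.csv(constraints_path, stringsAsFactors = FALSE)
    if (!all(c("mrca_of", "min_age") %in% names(constraints)))
      stop("constraints table needs columns mrca_of, min_age")
  }
  list(tree = tree, tip_ages = tip_ages, lads = lads, constraints = constraints)
}
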