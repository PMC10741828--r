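#' ROI atlas tables
#'
#' A `roi_atlas` is a data frame with one row per region of interest (ROI)
#' and columns `roi_id` (unique integer label), `name`, `hemisphere`
#' (`"L"` or `"R"`) and `subnetwork` (a functional subnetwork label such as
#' `"MAN"`, `"VN"`, `"AN"`, `"DMN"`, `"LSN"`). It defines the aggregation
#' units used throughout the laterality analysis: nodes, subnetwork-by-
#' hemisphere units, and hemispheres.
#'
#' @param roi_id integer vector of unique ROI labels.
#' @param name character vector of ROI names.
#' @param hemisphere character vector, each `"L"` or `"R"`.
#' @param subnetwork character vector of subnetwork labels.
#' @return A data frame of class `roi_atlas`.
#' @export
roi_atlas <- function(roi_id, name, hemisphere, subnetwork) {
  at <- data.frame(
    roi_id = as.integer(roi_id),
    name = as.character(name),
    hemisphere = as.character(hemisphere),
    subnetwork = as.character(subnetwork),
    stringsAsFactors = FALSE
  )
  class(at) <- c("roi_atlas", "data.frame")
  validate_atlas(at)
  at
}

validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  need <- c("roi_id", "name", "hemisphere", "subnetwork")
  missing_cols <- setdiff(need, names(atlas))
  if (length(missing_cols) > 0L) {
    stop("atlas lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(atlas$roi_id)) stop("atlas roi_id values must be unique")
  if (!all(atlas$hemisphere %in% c("L", "R"))) {
    stop("atlas hemisphere must be 'L' or 'R'")
  }
  if (!any(atlas$hemisphere == "L") || !any(atlas$hemisphere == "R")) {
    stop("both hemispheres must be non-empty")
  }
  if (anyNA(atlas$subnetwork)) stop("every ROI needs a subnetwork label")
  invisible(atlas)
}

#' Generate a homotopic two-hemisphere atlas
#'
#' Builds an atlas of `n_rois` regions split into equal left and right
#' halves (ROIs `1..n_rois/2` are left-hemisphere, the rest right), with
#' each hemisphere partitioned into the given subnetworks in contiguous,
#' near-equal blocks. Every subnetwork is present in both hemispheres, so
#' an atlas with 90 ROIs and 5 subnetworks yields the 12 standard
#' comparison units: 2 hemispheres plus 10 subnetwork-by-hemisphere units.
#'
#' @param n_rois even number of ROIs (default 90, mirroring the 90
#'   cerebral AAL regions).
#' @param subnetworks character vector of subnetwork labels (default the
#'   five within-hemisphere functional divisions MAN, VN, AN, DMN, LSN).
#' @return A `roi_atlas`.
#' @examples
#' at <- generate_atlas(90)
#' table(at$hemisphere)
#' @export
generate_atlas <- function(n_rois = 90L,
                           subnetworks = c("MAN", "VN", "AN", "DMN", "LSN")) {
  n_rois <- as.integer(n_rois)
  if (length(n_rois) != 1L || is.na(n_rois) || n_rois < 2L) {
    stop("n_rois must be a single integer >= 2")
  }
  if (n_rois %% 2L != 0L) {
    stop("n_rois must be even (equal left/right halves); got ", n_rois)
  }
  if (length(subnetworks) < 1L) stop("subnetwork list must be non-empty")
  if (anyDuplicated(subnetworks)) stop("subnetwork labels must be unique")
  half <- n_rois %/% 2L
  if (half < length(subnetworks)) {
    stop("each hemisphere needs at least one ROI per subnetwork")
  }
  # contiguous blocks per hemisphere, sizes differing by at most one
  sizes <- rep(half %/% length(subnetworks), length(subnetworks))
  extra <- half %% length(subnetworks)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  subnet_half <- rep(as.character(subnetworks), times = sizes)
  hemi <- rep(c("L", "R"), each = half)
  subnet <- c(subnet_half, subnet_half)
  roi_atlas(
    roi_id = seq_len(n_rois),
    name = sprintf("roi%03d_%s", seq_len(n_rois), hemi),
    hemisphere = hemi,
    subnetwork = subnet
  )
}

#' Swap hemisphere labels of an atlas
#'
#' Relabels every left ROI as right and vice versa. Used to state and test
#' the antisymmetry of the laterality index: computing DLI under the
#' flipped atlas negates every value.
#'
#' @param atlas a `roi_atlas`.
#' @return The atlas with `hemisphere` labels exchanged.
#' @export
flip_hemispheres <- function(atlas) {
  validate_atlas(atlas)
  atlas$hemisphere <- ifelse(atlas$hemisphere == "L", "R", "L")
  atlas
}

#' Read / write an atlas as tab-separated text
#'
#' The on-disk format is a TSV with header `roi_id name hemisphere
#' subnetwork`, one ROI per row.
#'
#' @param path file path.
#' @return `read_atlas()` returns a `roi_atlas`; `write_atlas()` returns
#'   `path` invisibly.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  roi_atlas(df$roi_id, df$name, df$hemisphere, df$subnetwork)
}

#' @rdname read_atlas
#' @param atlas a `roi_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# indices (into the atlas row order) of one hemisphere's ROIs
hemisphere_index <- function(atlas, side) {
  side <- match.arg(side, c("L", "R"))
  idx <- which(atlas$hemisphere == side)
  if (length(idx) == 0L) stop("hemisphere ", side, " has no ROIs")
  idx
}

#' Enumerate comparison units of an atlas
#'
#' @param atlas a `roi_atlas`.
#' @param level `"hemisphere"`, `"subnetwork"` (subnetwork-by-hemisphere)
#'   or `"node"`.
#' @return A data frame with columns `unit_id` and, per unit, the member
#'   `roi_id`s in a list column `members`.
#' @export
atlas_units <- function(atlas, level = c("subnetwork", "hemisphere", "node")) {
  level <- match.arg(level)
  validate_atlas(atlas)
  if (level == "node") {
    return(data.frame(unit_id = as.character(atlas$roi_id),
                      members = I(as.list(atlas$roi_id)),
                      stringsAsFactors = FALSE))
  }
  if (level == "hemisphere") {
    key <- atlas$hemisphere
    ids <- c("HEM_L", "HEM_R")[match(key, c("L", "R"))]
  } else {
    ids <- paste(atlas$subnetwork, atlas$hemisphere, sep = "_")
  }
  uid <- unique(ids)
  members <- lapply(uid, function(u) atlas$roi_id[ids == u])
  if (any(lengths(members) == 0L)) stop("unit with zero members")
  data.frame(unit_id = uid, members = I(members), stringsAsFactors = FALSE)
}
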