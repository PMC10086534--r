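# Neuromuscular-junction occupancy, terminal Schwann cell summaries and
# adipocyte morphometry from label masks.

NMJ_STATUSES <- c("occupied", "altered", "unoccupied")

#' Validate a table of NMJ annotation records
#'
#' @param records Data frame with columns `tissue`, `junction`, `status`
#'   (one of `"occupied"`, `"altered"`, `"unoccupied"`) and optionally
#'   `tsc_count` (nonnegative integer, `NA` when not co-stained).
#' @return The records, invisibly; errors name the violation.
#' @export
validate_nmj_records <- function(records) {
  req <- c("tissue", "junction", "status")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing NMJ record column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(records$status), NMJ_STATUSES)
  if (length(bad))
    stop("unknown NMJ status value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("tsc_count" %in% names(records)) {
    tc <- records$tsc_count
    if (any(!is.na(tc) & (tc < 0 | tc != floor(tc))))
      stop("`tsc_count` must be a nonnegative integer", call. = FALSE)
  }
  invisible(records)
}

#' Per-tissue NMJ occupancy and tSC summary
#'
#' `fraction_occupied` is the fraction of junctions scored fully occupied;
#' altered and unoccupied junctions both count as not fully occupied.
#' `mean_tsc_per_nmj` averages terminal-Schwann-cell counts over every record
#' that carries one (all statuses included). The conventional design scores
#' `expected_n = 50` junctions per tissue; a different count triggers a
#' warning, not an error.
#'
#' @param records Data frame as in [validate_nmj_records()].
#' @param expected_n Expected junctions per tissue (default 50).
#' @return Data frame with one row per tissue: `tissue`, `n_junctions`,
#'   `n_occupied`, `n_altered`, `n_unoccupied`, `fraction_occupied`,
#'   `mean_tsc_per_nmj`.
#' @export
nmj_summary <- function(records, expected_n = 50L) {
  if (is.null(records) || nrow(records) == 0L)
    stop("empty NMJ record list", call. = FALSE)
  validate_nmj_records(records)
  tissues <- unique(records$tissue)
  rows <- lapply(tissues, function(tid) {
    r <- records[records$tissue == tid, , drop = FALSE]
    n <- nrow(r)
    if (!is.null(expected_n) && n != expected_n)
      warning(sprintf("tissue '%s': %d junctions scored (expected %d)",
                      tid, n, expected_n), call. = FALSE)
    tsc <- if ("tsc_count" %in% names(r)) r$tsc_count[!is.na(r$tsc_count)] else numeric(0)
    data.frame(tissue = tid, n_junctions = n,
               n_occupied = sum(r$status == "occupied"),
               n_altered = sum(r$status == "altered"),
               n_unoccupied = sum(r$status == "unoccupied"),
               fraction_occupied = sum(r$status == "occupied") / n,
               mean_tsc_per_nmj = if (length(tsc)) mean(tsc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cell label mask
#'
#' @param labels Integer matrix, 0 = background, k > 0 = cell k.
#' @param pixel_size_um Micrometers per pixel edge.
#' @return Object of class `cell_label_mask`.
#' @export
cell_label_mask <- function(labels, pixel_size_um = 1) {
  if (!is.matrix(labels) || any(labels < 0) || any(labels != floor(labels)))
    stop("`labels` must be a matrix of nonnegative integers", call. = FALSE)
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0", call. = FALSE)
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "cell_label_mask")
}

#' Adipocyte area and perimeter from a label mask
#'
#' Area = pixel count times squared pixel size. Perimeter = outer pixel-edge
#' tracing: the number of unit edges between a cell pixel and anything that
#' is not the same cell (including the image border), times the pixel size.
#' Exact for axis-aligned shapes (a 10x10 square at 1 um/px gives area
#' 100 um^2 and perimeter 40 um).
#'
#' @param mask A [cell_label_mask()].
#' @return List with `per_cell` (data frame: `label`, `area_um2`,
#'   `perimeter_um`) and `means` (mean area and perimeter over cells).
#' @export
cell_metrics <- function(mask) {
  if (!inherits(mask, "cell_label_mask")) stop("`mask` must be a cell_label_mask", call. = FALSE)
  L <- mask$labels
  ids <- sort(unique(L[L > 0]))
  if (length(ids) == 0L) stop("label mask contains no cells", call. = FALSE)
  psz <- mask$pixel_size_um
  # pad with background so border pixels expose edges
  P <- matrix(0L, nrow(L) + 2L, ncol(L) + 2L)
  P[2:(nrow(L) + 1L), 2:(ncol(L) + 1L)] <- L
  edge_tally <- function(shifted) {
    core <- P[2:(nrow(L) + 1L), 2:(ncol(L) + 1L)]
    diff <- core > 0 & core != shifted
    tapply(rep(1L, sum(diff)), core[diff], sum)
  }
  up    <- P[1:nrow(L), 2:(ncol(L) + 1L)]
  down  <- P[3:(nrow(L) + 2L), 2:(ncol(L) + 1L)]
  left  <- P[2:(nrow(L) + 1L), 1:ncol(L)]
  right <- P[2:(nrow(L) + 1L), 3:(ncol(L) + 2L)]
  per_edges <- setNames(numeric(length(ids)), ids)
  for (sh in list(up, down, left, right)) {
    t_ <- edge_tally(sh)
    per_edges[names(t_)] <- per_edges[names(t_)] + t_
  }
  areas <- tapply(rep(1L, sum(L > 0)), L[L > 0], sum)
  per_cell <- data.frame(label = ids,
                         area_um2 = as.numeric(areas[as.character(ids)]) * psz^2,
                         perimeter_um = as.numeric(per_edges[as.character(ids)]) * psz)
  list(per_cell = per_cell,
       means = list(area_um2 = mean(per_cell$area_um2),
                    perimeter_um = mean(per_cell$perimeter_um)))
}

#' Advisory occupancy status from pre-/post-synaptic masks
#'
#' Coverage = fraction of the post-synaptic plaque overlapped by the
#' pre-synaptic terminal. The suggestion is advisory plumbing for manual
#' annotation, not an automated scoring claim: occupied when coverage is at
#' least `tau_occupied`, unoccupied when at most `tau_unoccupied`, otherwise
#' altered.
#'
#' @param pre_mask,post_mask Logical matrices of the same shape; `post_mask`
#'   nonempty.
#' @param tau_occupied,tau_unoccupied Decision thresholds (defaults 0.8, 0.2).
#' @return List with `coverage` and `status`.
#' @export
occupancy_score <- function(pre_mask, post_mask,
                            tau_occupied = 0.8, tau_unoccupied = 0.2) {
  pre <- as_mask(pre_mask); post <- as_mask(post_mask)
  if (!all(dim(pre) == dim(post))) stop("masks must share the same shape", call. = FALSE)
  npost <- sum(post)
  if (npost == 0L) stop("post-synaptic mask is empty", call. = FALSE)
  cov <- sum(pre & post) / npost
  status <- if (cov >= tau_occupied) "occupied"
            else if (cov <= tau_unoccupied) "unoccupied"
            else "altered"
  list(coverage = cov, status = status)
}
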