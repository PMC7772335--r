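#' Interval tracks (BED-style)
#'
#' Genomic intervals in 0-based half-open coordinates, optionally carrying a
#' numeric value (e.g. a recombination rate in cM/Mb). Tracks are normalized
#' on construction: sorted by contig and start. Overlapping intervals are
#' merged when `merge_overlaps = TRUE` (masks) and rejected otherwise
#' (value tracks, where overlap would make the annotation ambiguous).
#'
#' @param df Data frame with columns `contig`, `start`, `end` and optionally
#'   `value`.
#' @param merge_overlaps Merge overlapping/adjacent intervals (dropping any
#'   `value`)?
#' @return Tibble of class `interval_track`.
#' @export
interval_track <- function(df, merge_overlaps = FALSE) {
  df <- as_tibble(df)
  if (!all(c("contig", "start", "end") %in% names(df)))
    abort("interval track needs columns contig, start, end")
  df$start <- as.double(df$start)
  df$end <- as.double(df$end)
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    abort(paste0("interval with start >= end at row ", bad))
  }
  df <- arrange(df, .data$contig, .data$start, .data$end)
  ov <- with(df, contig == dplyr::lag(contig) & start < dplyr::lag(cummax_by(end, contig)))
  has_overlap <- any(ov, na.rm = TRUE)
  if (has_overlap) {
    if (!merge_overlaps) abort("overlapping intervals in value track")
    df <- merge_intervals(df)
  }
  structure(df, class = c("interval_track", class(tibble())))
}

# running max of end within contig (used for overlap detection)
cummax_by <- function(x, g) {
  unsplit(lapply(split(x, g), cummax), g)
}

merge_intervals <- function(df) {
  df %>%
    group_by(.data$contig) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                 default = -Inf))) %>%
    group_by(.data$contig, .data$grp) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    select("contig", "start", "end")
}

#' Read a BED file as a (merged) mask track
#'
#' Three-column tab-delimited BED, 0-based half-open; overlapping intervals
#' are merged.
#'
#' @param path File path.
#' @return An [interval_track()].
#' @examples
#' read_bed(system.file("extdata", "example_inversions.bed",
#'                      package = "splitmig"))
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !grepl("^(#|track|browser)", ln)]
  if (length(ln) == 0)
    return(interval_track(tibble(contig = character(), start = integer(),
                                 end = integer())))
  f <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(f) < 3)) abort("BED line with fewer than 3 fields")
  df <- tibble(contig = vapply(f, `[`, "", 1),
               start = as.integer(vapply(f, `[`, "", 2)),
               end = as.integer(vapply(f, `[`, "", 3)))
  bad <- which(df$start >= df$end)
  if (length(bad))
    abort(paste0("start >= end at line ", bad[1]))
  interval_track(df, merge_overlaps = TRUE)
}

#' Read a windowed recombination map
#'
#' Tab-delimited `contig start end rate` with rates in cM/Mb, 0-based
#' half-open windows; overlapping windows are an error (ambiguous rate).
#'
#' @param path File path.
#' @return An [interval_track()] with a `value` column.
#' @examples
#' read_recmap(system.file("extdata", "example_recmap.tsv",
#'                         package = "splitmig"))
#' @export
read_recmap <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(f) < 4)) abort("recombination map needs 4 columns")
  df <- tibble(contig = vapply(f, `[`, "", 1),
               start = as.integer(vapply(f, `[`, "", 2)),
               end = as.integer(vapply(f, `[`, "", 3)),
               value = as.double(vapply(f, `[`, "", 4)))
  bad <- which(df$start >= df$end | is.na(df$value))
  if (length(bad))
    abort(paste0("malformed recmap line ", bad[1]))
  interval_track(df, merge_overlaps = FALSE)
}

# For each (contig, pos) return the index of the covering interval in the
# normalized track, or NA.
locate_in_track <- function(contig, pos, track) {
  out <- rep(NA_integer_, length(pos))
  for (ctg in unique(contig)) {
    rows <- which(track$contig == ctg)
    sel <- which(contig == ctg)
    if (length(rows) == 0 || length(sel) == 0) next
    idx <- findInterval(pos[sel], track$start[rows])
    hit <- idx >= 1 & pos[sel] < track$end[rows][pmax(idx, 1)]
    out[sel[hit]] <- rows[idx[hit]]
  }
  out
}

#' Apply interval masks (and an optional keep track) to a dataset
#'
#' Removes sites falling inside any mask interval (e.g. inversion spans or
#' identity-by-descent runs) and, if `keep` is given (e.g. intron
#' annotation), sites outside every keep interval. Removal counts are logged
#' and recorded in the dataset provenance.
#'
#' @param ds A `hap_dataset`.
#' @param masks An [interval_track()] or list of them (may be empty).
#' @param keep Optional [interval_track()]; sites must fall inside it.
#' @return The filtered `hap_dataset`.
#' @export
apply_masks <- function(ds, masks = list(), keep = NULL) {
  if (inherits(masks, "interval_track")) masks <- list(masks)
  drop <- rep(FALSE, n_sites(ds))
  for (mk in masks) {
    stopifnot(inherits(mk, "interval_track"))
    drop <- drop | !is.na(locate_in_track(ds$sites$contig, ds$sites$pos, mk))
  }
  n_masked <- sum(drop)
  n_outside <- 0L
  if (!is.null(keep)) {
    stopifnot(inherits(keep, "interval_track"))
    inside <- !is.na(locate_in_track(ds$sites$contig, ds$sites$pos, keep))
    n_outside <- sum(!inside & !drop)
    drop <- drop | !inside
  }
  inform(paste0("apply_masks: removed ", n_masked, " masked site(s), ",
                n_outside, " outside keep track(s); ",
                sum(!drop), " retained"))
  subset_sites(ds, !drop,
               provenance = c(ds$provenance,
                              list(masked_out = n_masked,
                                   outside_keep = n_outside)))
}

subset_sites <- function(ds, sel, provenance = ds$provenance) {
  hap_dataset(geno = ds$geno[sel, , drop = FALSE],
              sites = ds$sites[sel, , drop = FALSE],
              samples = ds$samples, polarized = ds$polarized,
              provenance = provenance)
}

#' Annotate sites with a local recombination rate
#'
#' @param ds A `hap_dataset`.
#' @param recmap An [interval_track()] with rates in cM/Mb.
#' @return The dataset with a `rec_rate` site column; errors if any site is
#'   not covered by the map.
#' @export
annotate_recomb <- function(ds, recmap) {
  idx <- locate_in_track(ds$sites$contig, ds$sites$pos, recmap)
  if (anyNA(idx)) {
    k <- which(is.na(idx))[1]
    abort(paste0("site ", ds$sites$contig[k], ":", ds$sites$pos[k],
                 " not covered by the recombination map"))
  }
  ds$sites$rec_rate <- recmap$value[idx]
  ds
}

#' Partition a dataset into recombination-rate classes
#'
#' Splits sites into the classes `[0, 1.5)`, `[1.5, 3)` and `[3, 14.5]`
#' cM/Mb (boundaries assigned upward; the last class is closed). Uses the
#' dataset's `rec_rate` annotation, or `recmap` to create it.
#'
#' @param ds A `hap_dataset`.
#' @param recmap Optional [interval_track()] used when sites lack a
#'   `rec_rate` column.
#' @param breaks Class boundaries (default `c(0, 1.5, 3, 14.5)`).
#' @return Named list of `hap_dataset`, one per class (empty classes
#'   included); the union of the outputs is the input.
#' @export
partition_by_recomb <- function(ds, recmap = NULL, breaks = c(0, 1.5, 3, 14.5)) {
  if (!"rec_rate" %in% names(ds$sites)) {
    if (is.null(recmap)) abort("no rec_rate annotation and no recmap given")
    ds <- annotate_recomb(ds, recmap)
  }
  r <- ds$sites$rec_rate
  if (any(r < breaks[1] | r > breaks[length(breaks)]))
    abort("recombination rate outside the class range")
  cls <- findInterval(r, breaks, rightmost.closed = TRUE)
  k <- length(breaks) - 1L
  labs <- paste0("[", breaks[-length(breaks)], ",", breaks[-1],
                 c(rep(")", k - 1), "]"))
  out <- lapply(seq_len(k), function(ii) subset_sites(ds, cls == ii))
  names(out) <- labs
  out
}
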