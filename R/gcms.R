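#' Chemical-class vocabulary for GC-MS peaks
#' @export
CHEMICAL_CLASSES <- c("aldehyde", "alcohol", "ketone", "alkane", "ester",
                      "alkene", "carboxylic acid", "ether", "other")

#' GC-MS peak table
#'
#' One integrated chromatogram: rows of (retention time, compound,
#' chemical class, area). Areas are non-negative; rows are kept in
#' non-decreasing retention-time order.
#'
#' @param df Data frame with columns `retention_time_min`, `compound`,
#'   `chemical_class`, `area`.
#' @param sample_id,replicate_id Metadata attached as attributes.
#' @return The validated data frame with class `peak_table`.
#' @export
peak_table <- function(df, sample_id = NA_character_, replicate_id = NA) {
  needed <- c("retention_time_min", "compound", "chemical_class", "area")
  if (!all(needed %in% names(df)))
    stop("peak table lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$chemical_class), CHEMICAL_CLASSES)
  if (length(bad))
    stop("unknown chemical classes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(df$area < 0)) stop("areas must be >= 0", call. = FALSE)
  df <- df[order(df$retention_time_min), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_table", "data.frame"),
            sample_id = sample_id, replicate_id = replicate_id)
}

#' Filter integrated peaks by minimum area
#'
#' Keeps peaks whose area is not less than `min_area` (the boundary value
#' itself is retained). The surviving-peak count is compared against
#' `min_peaks` as a quality-control check: too few peaks flags the table
#' (`qc_pass` attribute FALSE, with a warning) but the filtered table is
#' still returned -- small synthetic tables are legitimate.
#'
#' @param tbl A [peak_table()].
#' @param min_area Minimum integrated area to retain (default 500 AMU).
#' @param min_peaks QC threshold on the surviving peak count (default 70).
#' @return Filtered `peak_table` with attribute `qc_pass`.
#' @export
filter_peaks <- function(tbl, min_area = 500, min_peaks = 70) {
  stopifnot(inherits(tbl, "peak_table"))
  if (min_area < 0) stop("min_area must be >= 0", call. = FALSE)
  keep <- tbl$area >= min_area
  out <- tbl[keep, , drop = FALSE]
  qc <- nrow(out) >= min_peaks
  if (!qc)
    warning(sprintf("only %d peaks survive the %.0f-area filter (QC expects >= %d)",
                    nrow(out), min_area, min_peaks), call. = FALSE)
  out <- peak_table(as.data.frame(out), sample_id = attr(tbl, "sample_id"),
                    replicate_id = attr(tbl, "replicate_id"))
  attr(out, "qc_pass") <- qc
  out
}

#' Relative abundance (% GC area)
#'
#' Expresses each peak's area as a percentage of the summed area of all
#' retained peaks; the column sums to 100 and is invariant to rescaling all
#' areas by a common factor.
#'
#' @param tbl A [peak_table()] (usually after [filter_peaks()]).
#' @return The table with an added `rel_abundance` column (percent).
#' @export
relative_abundance <- function(tbl) {
  stopifnot(inherits(tbl, "peak_table"))
  total <- sum(tbl$area)
  if (!is.finite(total) || total <= 0)
    stop("total peak area must be > 0", call. = FALSE)
  tbl$rel_abundance <- 100 * tbl$area / total
  tbl
}

#' Aggregate replicate chromatograms into a class profile
#'
#' Matches compounds across replicates by exact name, treats a compound
#' absent from a replicate as 0% there (so mean and SD are well defined;
#' `absent_as_zero = FALSE` switches to present-only averaging), and
#' reports per-compound mean and sample SD of relative abundance plus
#' per-chemical-class compound counts and mean abundance totals.
#'
#' @param replicates List of [peak_table()]s for one sample (e.g. the
#'   triplicate vials); `rel_abundance` is computed where missing.
#' @param absent_as_zero Treat missing compounds as 0% (default) or drop
#'   them from that replicate's average.
#' @return Object of class `class_profile`: `compounds` (compound,
#'   chemical_class, mean_pct, sd_pct, n_present), `classes`
#'   (chemical_class, n_compounds, mean_pct), `n_replicates`.
#' @export
aggregate_replicates <- function(replicates, absent_as_zero = TRUE) {
  if (length(replicates) == 0L)
    stop("need at least one replicate", call. = FALSE)
  replicates <- lapply(replicates, function(tb) {
    stopifnot(inherits(tb, "peak_table"))
    if (!"rel_abundance" %in% names(tb)) relative_abundance(tb) else tb
  })
  comp <- unique(do.call(rbind, lapply(replicates, function(tb)
    data.frame(compound = tb$compound, chemical_class = tb$chemical_class,
               stringsAsFactors = FALSE))))
  if (anyDuplicated(comp$compound))
    stop("a compound maps to more than one chemical class across replicates",
         call. = FALSE)
  M <- sapply(replicates, function(tb) {
    v <- rep(if (absent_as_zero) 0 else NA_real_, nrow(comp))
    v[match(tb$compound, comp$compound)] <- tb$rel_abundance
    v
  })
  M <- matrix(M, nrow = nrow(comp))
  mean_pct <- rowMeans(M, na.rm = TRUE)
  sd_pct <- apply(M, 1, stats::sd, na.rm = TRUE)
  sd_pct[is.na(sd_pct)] <- 0   # single observation: SD undefined, report 0
  n_present <- rowSums(!is.na(M) & M > 0)

  compounds <- data.frame(compound = comp$compound,
                          chemical_class = comp$chemical_class,
                          mean_pct = mean_pct, sd_pct = sd_pct,
                          n_present = n_present, stringsAsFactors = FALSE)
  compounds <- compounds[order(compounds$chemical_class,
                               -compounds$mean_pct), ]
  rownames(compounds) <- NULL
  present <- compounds[compounds$mean_pct > 0, ]
  classes <- data.frame(
    chemical_class = CHEMICAL_CLASSES,
    n_compounds = vapply(CHEMICAL_CLASSES, function(cc)
      sum(present$chemical_class == cc), integer(1)),
    mean_pct = vapply(CHEMICAL_CLASSES, function(cc)
      sum(compounds$mean_pct[compounds$chemical_class == cc]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(compounds = compounds, classes = classes,
                 n_replicates = length(replicates)),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat("VOC class profile (", x$n_replicates, " replicates)\n", sep = "")
  print(x$classes[x$classes$n_compounds > 0, ])
  invisible(x)
}

#' Compare two VOC profiles (e.g. raw vs cooked)
#'
#' Per chemical class, the compound-count difference and the
#' mean-abundance difference (second profile minus first), plus the lists
#' of compounds detected in only one of the two profiles.
#'
#' @param profile_a First [aggregate_replicates()] profile (e.g. raw).
#' @param profile_b Second profile (e.g. cooked); deltas are `b - a`.
#' @return List: `by_class` (chemical_class, count_delta,
#'   mean_abundance_delta), `only_in_b`, `only_in_a` (compound names).
#' @export
compare_states <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "class_profile"),
            inherits(profile_b, "class_profile"))
  ca <- profile_a$classes
  cb <- profile_b$classes
  by_class <- data.frame(
    chemical_class = CHEMICAL_CLASSES,
    count_delta = cb$n_compounds[match(CHEMICAL_CLASSES,
                                       cb$chemical_class)] -
      ca$n_compounds[match(CHEMICAL_CLASSES, ca$chemical_class)],
    mean_abundance_delta = cb$mean_pct[match(CHEMICAL_CLASSES,
                                             cb$chemical_class)] -
      ca$mean_pct[match(CHEMICAL_CLASSES, ca$chemical_class)],
    stringsAsFactors = FALSE)
  pres_a <- profile_a$compounds$compound[profile_a$compounds$mean_pct > 0]
  pres_b <- profile_b$compounds$compound[profile_b$compounds$mean_pct > 0]
  list(by_class = by_class,
       only_in_b = setdiff(pres_b, pres_a),
       only_in_a = setdiff(pres_a, pres_b))
}

#' Write / read a peak table as delimited text
#'
#' Tab-separated with columns `retention_time_min`, `compound`,
#' `chemical_class`, `area` (plus `rel_abundance` when present).
#'
#' @param tbl A [peak_table()].
#' @param path File path.
#' @return `write_peak_table()` returns `path` invisibly;
#'   `read_peak_table()` returns a `peak_table`.
#' @export
write_peak_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "peak_table"))
  utils::write.table(as.data.frame(tbl), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @param sample_id,replicate_id Metadata for the restored table.
#' @export
read_peak_table <- function(path, sample_id = NA_character_,
                            replicate_id = NA) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  peak_table(df, sample_id = sample_id, replicate_id = replicate_id)
}
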