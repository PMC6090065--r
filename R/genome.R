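# Post-processing filters on resequencing mutation calls and the
# coverage-based duplication heuristic.

#' Default gene deny list for mutation filtering
#'
#' Genes and loci prone to repeat-driven miscalls in short-read population
#' resequencing: crl, the insertion-element genes, and the rhs/rsx loci.
#' Entries are glob patterns matched against the record's gene label.
#'
#' @return Character vector of glob patterns.
#' @export
default_gene_denylist <- function() {
  c("crl", "insH*", "insB*", "insA", "rhs*", "rsx*")
}

#' Filter a mutation call table
#'
#' Removes records with `frequency < min_freq` OR `p_value > max_p` OR
#' `quality < min_qual` OR a gene matching the deny list. Comparisons are
#' strict, so a record exactly at a threshold survives. The filter is
#' idempotent and its output is a subset of its input.
#'
#' @param records data.frame with columns `position` (1-based), `frequency`
#'   (fraction in `[0, 1]`), `p_value`, `quality` (>= 0), `gene` (label or
#'   NA).
#' @param min_freq,max_p,min_qual thresholds (defaults 0.1, 0.01, 6.0).
#' @param deny_genes glob patterns; see [default_gene_denylist()].
#' @return list with `kept` (surviving records) and `report` (dropped
#'   records with a `reason` column).
#' @export
filter_mutations <- function(records, min_freq = 0.1, max_p = 0.01,
                             min_qual = 6.0,
                             deny_genes = default_gene_denylist()) {
  need <- c("position", "frequency", "p_value", "quality")
  if (!all(need %in% names(records)))
    stop_fluxpath("format", paste0("mutation table needs columns: ",
                                   paste(need, collapse = ", ")))
  if (!"gene" %in% names(records)) records$gene <- NA_character_
  if (any(records$frequency < 0 | records$frequency > 1, na.rm = TRUE))
    stop_fluxpath("validation", "frequency must lie in [0, 1]")
  if (any(records$quality < 0, na.rm = TRUE))
    stop_fluxpath("validation", "quality must be >= 0")
  denied <- rep(FALSE, nrow(records))
  for (pat in deny_genes)
    denied <- denied | (!is.na(records$gene) &
                          grepl(utils::glob2rx(pat), records$gene))
  reason <- character(nrow(records))
  reason[records$quality < min_qual] <- "low_quality"
  reason[records$p_value > max_p] <- "high_p_value"
  reason[records$frequency < min_freq] <- "low_frequency"
  reason[denied] <- "deny_list_gene"
  drop <- reason != ""
  report <- records[drop, , drop = FALSE]
  if (nrow(report)) report$reason <- reason[drop]
  else report$reason <- character()
  list(kept = records[!drop, , drop = FALSE], report = report)
}

#' Call duplicated regions from a coverage track
#'
#' Reports maximal runs of consecutive positions whose depth exceeds
#' `factor` times the track-wide mean depth, keeping runs of at least
#' `min_len` positions (default 200). Calls are disjoint, sorted and
#' maximal.
#'
#' @param depths non-negative integer depths over a contiguous 1-based
#'   interval.
#' @param min_len minimum run length.
#' @param factor depth multiple of the mean defining "elevated" (strictly
#'   greater).
#' @param offset genome coordinate of the first element of `depths`
#'   (default 1), so tracks for arbitrary windows can be scanned.
#' @return data.frame with `start`, `end` (1-based inclusive),
#'   `mean_depth`, `length`.
#' @export
call_duplications <- function(depths, min_len = 200L, factor = 2.0,
                              offset = 1L) {
  if (length(depths) < 1L)
    stop_fluxpath("validation", "empty coverage track")
  if (any(depths < 0))
    stop_fluxpath("validation", "depths must be >= 0")
  thr <- factor * mean(depths)
  above <- depths > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  out <- data.frame(
    start = starts[keep] + offset - 1L,
    end = ends[keep] + offset - 1L,
    mean_depth = vapply(keep, function(k)
      mean(depths[starts[k]:ends[k]]), numeric(1)),
    length = r$lengths[keep])
  rownames(out) <- NULL
  out
}

#' Read a mutation table from TSV
#'
#' Columns `position`, `frequency`, `p_value`, `quality`, `gene` — the
#' tabular export format of population variant callers.
#'
#' @param path TSV file.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Read a coverage track from two-column TSV
#'
#' Columns `position`, `depth`; positions must be contiguous and ascending.
#'
#' @param path TSV file.
#' @return list with `depths` (integer vector) and `offset` (first
#'   position).
#' @export
read_coverage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("position", "depth") %in% names(df)))
    stop_fluxpath("format", "coverage TSV needs columns position, depth")
  if (nrow(df) > 1L && any(diff(df$position) != 1L))
    stop_fluxpath("format", "coverage positions must be contiguous")
  list(depths = as.numeric(df$depth), offset = as.integer(df$position[1]))
}

#' Write duplication calls as BED
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention.
#'
#' @param calls output of [call_duplications()].
#' @param path BED output path.
#' @param chrom chromosome/replicon name for the BED records.
#' @return `path`, invisibly.
#' @export
write_duplications_bed <- function(calls, path, chrom = "chr") {
  bed <- data.frame(chrom = chrom,
                    start = calls$start - 1L,  # 0-based half-open
                    end = calls$end,
                    name = sprintf("dup_%d", seq_len(nrow(calls))),
                    score = round(calls$mean_depth, 2))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
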