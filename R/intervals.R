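# Consolidation of per-trait QTL calls into non-overlapping genetic
# intervals and clustered qSC intervals, and their projection onto
# physical contig segments.
#
# Overlap convention: intervals are half-open [start, end) so that
# endpoint-touching intervals stay distinct, except that a degenerate
# (zero-length) interval merges into any interval whose closed range
# contains its point. cM values are carried at 2-decimal precision
# (integer hundredths internally) to avoid float-equality artifacts.

.cm100 <- function(x) as.integer(round(x * 100))

#' Genetic intervals from QTL calls
#'
#' Extracts the flanking-marker cM boundaries of each QTL call as a
#' genetic interval annotated with its QTL name and trait.
#' @param calls QTL call data frame from [call_qtls()] (or any table with
#'   columns group, left_cM, right_cM, name, trait).
#' @return data frame group, start, end, qtls, traits.
#' @export
qtl_intervals <- function(calls) {
  data.frame(group = calls$group, start = calls$left_cM,
             end = calls$right_cM, qtls = calls$name,
             traits = calls$trait, stringsAsFactors = FALSE)
}

.paste_uniq <- function(x) paste(unique(unlist(strsplit(x, ","))),
                                 collapse = ",")

#' Merge overlapping QTL intervals into non-overlapping intervals
#'
#' Per linkage group, identical intervals are deduplicated and intervals
#' overlapping as half-open ranges are merged to their union; a
#' zero-length interval is absorbed by any interval whose closed range
#' contains it. The output is sorted, pairwise disjoint, and annotated
#' with all supporting QTLs and traits.
#'
#' @param intervals data frame group, start, end (cM), optional qtls,
#'   traits.
#' @return merged data frame with the same columns.
#' @export
merge_overlapping <- function(intervals) {
  if (any(intervals$start > intervals$end)) stop("interval start > end")
  iv <- intervals
  iv$qtls <- iv$qtls %||% rep("", nrow(iv))
  iv$traits <- iv$traits %||% rep("", nrow(iv))
  out <- list()
  for (g in unique(iv$group)) {
    sub <- iv[iv$group == g, , drop = FALSE]
    s <- .cm100(sub$start); e <- .cm100(sub$end)
    o <- order(s, e)
    sub <- sub[o, ]; s <- s[o]; e <- e[o]
    cs <- s[1]; ce <- e[1]; q <- sub$qtls[1]; tr <- sub$traits[1]
    flush <- function() {
      out[[length(out) + 1L]] <<- data.frame(
        group = g, start = cs / 100, end = ce / 100,
        qtls = .paste_uniq(q), traits = .paste_uniq(tr),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(sub))[-1]) {
      # half-open overlap, or a point touching a closed endpoint
      merges <- s[i] < ce ||
        (s[i] == ce && (s[i] == e[i] || cs == ce))
      if (merges) {
        ce <- max(ce, e[i])
        q <- paste(q, sub$qtls[i], sep = ",")
        tr <- paste(tr, sub$traits[i], sep = ",")
      } else {
        flush()
        cs <- s[i]; ce <- e[i]; q <- sub$qtls[i]; tr <- sub$traits[i]
      }
    }
    flush()
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster adjacent intervals into spanning qSC intervals
#'
#' Per linkage group, chains of disjoint intervals whose inter-interval
#' gap is at most `max_gap` cM are merged into one spanning interval
#' (the QTL-hotspot consolidation step).
#'
#' @param intervals disjoint, sorted intervals from
#'   [merge_overlapping()].
#' @param max_gap maximum gap bridged, in cM (default 2).
#' @return clustered data frame group, start, end, qtls, traits.
#' @export
cluster_adjacent <- function(intervals, max_gap = 2) {
  iv <- intervals
  gap100 <- .cm100(max_gap)
  out <- list()
  for (g in unique(iv$group)) {
    sub <- iv[iv$group == g, , drop = FALSE]
    s <- .cm100(sub$start); e <- .cm100(sub$end)
    o <- order(s, e)
    sub <- sub[o, ]; s <- s[o]; e <- e[o]
    cs <- s[1]; ce <- e[1]; q <- sub$qtls[1]; tr <- sub$traits[1]
    flush <- function() {
      out[[length(out) + 1L]] <<- data.frame(
        group = g, start = cs / 100, end = ce / 100,
        qtls = .paste_uniq(q), traits = .paste_uniq(tr),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(sub))[-1]) {
      if (s[i] - ce <= gap100) {
        ce <- max(ce, e[i])
        q <- paste(q, sub$qtls[i], sep = ",")
        tr <- paste(tr, sub$traits[i], sep = ",")
      } else {
        flush()
        cs <- s[i]; ce <- e[i]; q <- sub$qtls[i]; tr <- sub$traits[i]
      }
    }
    flush()
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Project a genetic interval onto physical contig segments
#'
#' Returns the physical bp range spanned by the bins whose cM positions
#' fall inside the interval (closed, at 2-decimal precision), split into
#' one segment per contig.
#'
#' @param interval one-row data frame (group, start, end in cM).
#' @param map a spaced `genetic_map`.
#' @return data frame contig, start_bp, end_bp, group, start_cM, end_cM.
#' @export
to_physical <- function(interval, map) {
  tab <- map$table
  g <- interval$group[1]
  if (!g %in% tab$group) stop("group not in map")
  cm <- .cm100(tab$cM)
  sel <- tab$group == g & cm >= .cm100(interval$start[1]) &
    cm <= .cm100(interval$end[1])
  if (!any(sel)) stop("interval contains no bins")
  bt <- tab[sel, , drop = FALSE]
  segs <- do.call(rbind, lapply(unique(bt$contig), function(ct) {
    data.frame(contig = ct,
               start_bp = min(bt$start_bp[bt$contig == ct]),
               end_bp = max(bt$end_bp[bt$contig == ct]),
               group = g, start_cM = interval$start[1],
               end_cM = interval$end[1], stringsAsFactors = FALSE)
  }))
  rownames(segs) <- NULL
  segs
}

#' Parse `contig-bp` marker identifiers
#'
#' Splits marker names of the form `<contig>-<bp>` (the contig itself may
#' contain hyphens or underscores; the final hyphen-delimited field is
#' the position).
#' @param ids character vector of marker ids.
#' @return data frame contig, pos.
#' @export
parse_marker_id <- function(ids) {
  pos <- as.integer(sub(".*-", "", ids))
  contig <- sub("-[0-9]+$", "", ids)
  data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
}

#' Write physical segments as BED (0-based half-open)
#' @param segments data frame from [to_physical()].
#' @param path BED file.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(segments$contig, segments$start_bp - 1L,
                    segments$end_bp,
                    sprintf("LG%s_%.2f-%.2f", segments$group,
                            segments$start_cM, segments$end_cM))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
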