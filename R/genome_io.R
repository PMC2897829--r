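# Readers and writers for the external formats the toolkit touches.
# All coordinates are converted on ingest to the internal 0-based
# half-open convention (see coords.R) and back on output.

#' Read a probe-level log-ratio matrix
#'
#' Expects a tab-delimited file with a header row and columns
#' `probe_id`, `chromosome`, `position`, then one log-ratio column per
#' sample. Rows with a missing log-ratio are dropped per sample and the
#' drop count reported via `message()`.
#'
#' @param path path to the tab-delimited probe matrix.
#' @return named list of probe profiles, one per sample. Each profile is a
#'   `data.frame` with columns `chrom`, `pos`, `lr`, sorted by chromosome
#'   then position, with attributes `sample_id` and `n_dropped`.
#' @export
read_probe_profiles <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "position")
  if (!all(need %in% names(tab))) {
    stop("probe matrix must have columns probe_id, chromosome, position; missing: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(tab$position))
  if (anyNA(pos)) {
    stop("unparseable position at line ", which(is.na(pos))[1] + 1L)
  }
  chrom <- norm_chrom(tab$chromosome)
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    stop("duplicated (chromosome, position) at line ",
         which(duplicated(key))[1] + 1L)
  }
  samples <- setdiff(names(tab), need)
  ord <- order(chrom, pos)
  out <- lapply(samples, function(s) {
    lr <- suppressWarnings(as.numeric(tab[[s]]))
    keep <- !is.na(lr)
    n_drop <- sum(!keep)
    if (n_drop > 0) {
      message("sample ", s, ": dropped ", n_drop, " probes with missing log-ratio")
    }
    oo <- ord[keep[ord]]
    prof <- data.frame(chrom = chrom[oo], pos = pos[oo], lr = lr[oo],
                       stringsAsFactors = FALSE)
    rownames(prof) <- NULL
    attr(prof, "sample_id") <- s
    attr(prof, "n_dropped") <- n_drop
    prof
  })
  names(out) <- samples
  out
}

#' Write a probe profile list back to the probe-matrix format
#'
#' Inverse of [read_probe_profiles()] for profiles sharing one probe grid.
#' @param profiles named list of profiles as returned by [read_probe_profiles()].
#' @param path output path.
#' @export
write_probe_profiles <- function(profiles, path) {
  stopifnot(length(profiles) >= 1)
  base <- profiles[[1]]
  tab <- data.frame(probe_id = paste0("P", seq_len(nrow(base))),
                    chromosome = base$chrom, position = base$pos,
                    stringsAsFactors = FALSE)
  for (s in names(profiles)) {
    p <- profiles[[s]]
    if (!identical(p$chrom, base$chrom) || !identical(p$pos, base$pos)) {
      stop("write_probe_profiles requires a shared probe grid")
    }
    tab[[s]] <- p$lr
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a SEG-format segmentation table
#'
#' SEG dialect: tab-delimited with header `ID`, `chrom`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean`; input coordinates 1-based inclusive,
#' converted to internal 0-based half-open on load. Per-sample segments are
#' sorted and checked for overlap.
#'
#' @param path path to the SEG file.
#' @return named list (by sample) of `data.frame`s with columns
#'   `sample`, `chrom`, `start`, `end`, `n_markers`, `mean`.
#' @export
read_seg <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("SEG file must have 6 columns")
  names(tab)[1:6] <- c("sample", "chrom", "start", "end", "n_markers", "mean")
  conv <- to_internal(tab$start, tab$end)
  seg <- data.frame(sample = as.character(tab$sample),
                    chrom = norm_chrom(tab$chrom),
                    start = conv$start, end = conv$end,
                    n_markers = as.integer(tab$n_markers),
                    mean = as.numeric(tab$mean),
                    stringsAsFactors = FALSE)
  if (any(seg$end <= seg$start)) {
    stop("segment with end <= start at row ", which(seg$end <= seg$start)[1])
  }
  out <- split(seg, seg$sample)
  out <- lapply(out, function(d) {
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    rownames(d) <- NULL
    validate_segments(d)
    d
  })
  out[unique(seg$sample)]
}

#' Check that segments of one sample are non-overlapping within chromosome
#' @keywords internal
validate_segments <- function(seg) {
  for (ch in unique(seg$chrom)) {
    d <- seg[seg$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1) {
      bad <- which(d$start[-1] < d$end[-nrow(d)])
      if (length(bad)) {
        stop(sprintf("overlapping segments in sample %s chrom %s: [%d,%d) and [%d,%d)",
                     d$sample[1], ch,
                     d$start[bad[1]], d$end[bad[1]],
                     d$start[bad[1] + 1], d$end[bad[1] + 1]))
      }
    }
  }
  invisible(TRUE)
}

#' Write segments as a SEG file (coordinates converted back to 1-based)
#' @param segments data.frame or list of data.frames with the segment columns.
#' @param path output path.
#' @export
write_seg <- function(segments, path) {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- do.call(rbind, segments)
  }
  ext <- to_external(segments$start, segments$end)
  tab <- data.frame(ID = segments$sample, chrom = segments$chrom,
                    loc.start = ext$start, loc.end = ext$end,
                    num.mark = segments$n_markers, seg.mean = segments$mean)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Default column map for a DGV v7-style text dump
#' @export
dgv_default_column_map <- function() {
  c(variation_id = "VariationID", chromosome = "Chr",
    start = "Start", end = "End", study_id = "Reference",
    n_individuals = "SampleSize")
}

#' Read a DGV-style variant table
#'
#' Tab-delimited with header; `column_map` names the physical columns
#' holding each logical field (`n_individuals` optional). Input coordinates
#' are 1-based inclusive; converted on load.
#'
#' @param path path to the table.
#' @param column_map named character vector mapping logical fields
#'   (`variation_id`, `chromosome`, `start`, `end`, `study_id`, optionally
#'   `n_individuals`) to physical column names.
#' @param annotation optional [read_annotations()] result; records on
#'   chromosomes absent from it are kept but flagged in column `off_annotation`.
#' @return `data.frame` with columns `variation_id`, `chrom`, `start`, `end`,
#'   `study_id`, `n_individuals` (NA where absent), `off_annotation`.
#' @export
read_dgv <- function(path, column_map = dgv_default_column_map(),
                     annotation = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("variation_id", "chromosome", "start", "end", "study_id")
  for (f in need) {
    if (!f %in% names(column_map) || !(column_map[[f]] %in% names(tab))) {
      stop("DGV column map: missing mapped column for ", f)
    }
  }
  conv <- to_internal(tab[[column_map[["start"]]]], tab[[column_map[["end"]]]])
  n_ind <- rep(NA_real_, nrow(tab))
  if ("n_individuals" %in% names(column_map) &&
      column_map[["n_individuals"]] %in% names(tab)) {
    n_ind <- suppressWarnings(as.numeric(tab[[column_map[["n_individuals"]]]]))
  }
  dgv <- data.frame(variation_id = as.character(tab[[column_map[["variation_id"]]]]),
                    chrom = norm_chrom(tab[[column_map[["chromosome"]]]]),
                    start = conv$start, end = conv$end,
                    study_id = as.character(tab[[column_map[["study_id"]]]]),
                    n_individuals = n_ind,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(dgv$variation_id)) {
    stop("duplicate variation_id: ",
         dgv$variation_id[duplicated(dgv$variation_id)][1])
  }
  if (any(dgv$end <= dgv$start)) stop("DGV record with end <= start")
  dgv$off_annotation <- if (is.null(annotation)) FALSE else
    !(dgv$chrom %in% names(annotation$chrom_lengths))
  dgv
}

#' Read annotation intervals and chromosome lengths
#'
#' @param chrom_lengths_path two-column tab-delimited file: chromosome, length.
#' @param centromere_path 3-column BED (0-based half-open) of centromere
#'   intervals, one per chromosome; optional.
#' @param segdup_path BED of segmental-duplication regions; optional.
#' @param physiological_path BED of physiological exclusion regions; optional.
#' @return list with `chrom_lengths` (named numeric), `centromeres`,
#'   `segdups`, `physiological` (each a data.frame `chrom`,`start`,`end`).
#' @export
read_annotations <- function(chrom_lengths_path, centromere_path = NULL,
                             segdup_path = NULL, physiological_path = NULL) {
  cl <- utils::read.delim(chrom_lengths_path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  lens <- as.numeric(cl[[2]])
  names(lens) <- norm_chrom(cl[[1]])
  read_bed <- function(p) {
    if (is.null(p)) {
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), stringsAsFactors = FALSE))
    }
    info <- file.info(p)
    if (!is.na(info$size) && info$size == 0) {
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), stringsAsFactors = FALSE))
    }
    b <- utils::read.delim(p, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    d <- data.frame(chrom = norm_chrom(b[[1]]), start = as.numeric(b[[2]]),
                    end = as.numeric(b[[3]]), stringsAsFactors = FALSE)
    bad <- d$chrom %in% names(lens) & d$end > lens[d$chrom]
    if (any(bad)) {
      stop("annotation interval past chromosome end: ", d$chrom[bad][1],
           ":", d$start[bad][1], "-", d$end[bad][1])
    }
    d
  }
  list(chrom_lengths = lens,
       centromeres = read_bed(centromere_path),
       segdups = read_bed(segdup_path),
       physiological = read_bed(physiological_path))
}

#' Construct an annotation object in code (no files)
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param centromeres,segdups,physiological data.frames with columns
#'   `chrom`, `start`, `end` in internal coordinates; may be NULL.
#' @export
make_annotation <- function(chrom_lengths, centromeres = NULL,
                            segdups = NULL, physiological = NULL) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  fix <- function(d) {
    if (is.null(d) || nrow(d) == 0) return(empty)
    d$chrom <- norm_chrom(d$chrom)
    bad <- d$chrom %in% names(chrom_lengths) & d$end > chrom_lengths[d$chrom]
    if (any(bad)) stop("annotation interval past chromosome end")
    d[, c("chrom", "start", "end")]
  }
  names(chrom_lengths) <- norm_chrom(names(chrom_lengths))
  list(chrom_lengths = chrom_lengths, centromeres = fix(centromeres),
       segdups = fix(segdups), physiological = fix(physiological))
}

#' Write the per-candidate report TSV
#'
#' One row per candidate: sample, chromosome, 1-based start/end, segment
#' mean, all feature columns, predicted class and (when supplied) the true
#' class. Column order is: sample, chrom, start, end, mean, the feature
#' matrix columns in their fixed order, predicted, truth.
#'
#' @param candidates candidate data.frame (internal coordinates).
#' @param features feature matrix from [build_feature_matrix()], aligned
#'   row-for-row with `candidates`.
#' @param predicted character vector of predicted classes ("CNV"/"CNA").
#' @param truth optional character vector of true classes.
#' @param path output path.
#' @export
write_report <- function(candidates, features, predicted, truth = NULL, path) {
  n <- nrow(candidates)
  if (nrow(features) != n || length(predicted) != n ||
      (!is.null(truth) && length(truth) != n)) {
    stop("write_report: length mismatch between candidates, features and classes")
  }
  ext <- to_external(candidates$start, candidates$end)
  tab <- data.frame(sample = candidates$sample, chrom = candidates$chrom,
                    start = ext$start, end = ext$end, mean = candidates$mean,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, features[, feature_columns(), drop = FALSE])
  tab$predicted <- as.character(predicted)
  if (!is.null(truth)) tab$truth <- as.character(truth)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
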