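#' @title File dialects
#' @name io
#' @description Readers and writers for the plain-text dialects the analysis
#'   stages exchange: inclusion (PSI) tables with quality columns, sample-to-
#'   tissue-group configs, per-second activity exports, per-minute zone
#'   exports, trajectory CSVs, and GMT gene-set files.
NULL

#' Read a PSI inclusion table (TSV)
#'
#' Expects columns `EVENT`, `GENE`, `LENGTH`, then per-sample column pairs:
#' the PSI value (column named after the sample) and a quality string whose
#' first comma-separated field is the coverage code (column `<sample>.Q`), as
#' in inclusion tables produced by splicing quantifiers.
#'
#' @param path TSV file path.
#' @return A [psi_table()].
#' @export
read_psi_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("EVENT", "GENE", "LENGTH") %in% names(d)))
  cols <- setdiff(names(d), c("EVENT", "GENE", "LENGTH"))
  qcols <- grep("\\.Q$", cols, value = TRUE)
  samples <- sub("\\.Q$", "", qcols)
  stopifnot(all(samples %in% cols))
  psi <- as.matrix(d[, samples, drop = FALSE])
  qual <- vapply(qcols, function(qc) {
    vapply(strsplit(as.character(d[[qc]]), ","), `[`, character(1), 1L)
  }, character(nrow(d)))
  if (nrow(d) == 1L) qual <- matrix(qual, nrow = 1L)
  colnames(qual) <- samples
  psi_table(
    events = data.frame(event_id = d$EVENT, gene_id = d$GENE,
                        exon_length_nt = d$LENGTH),
    psi = psi, quality = qual)
}

#' Write a PSI inclusion table (TSV)
#'
#' @param table A [psi_table()].
#' @param path Output TSV path.
#' @export
write_psi_table <- function(table, path) {
  d <- data.frame(EVENT = table$events$event_id,
                  GENE = table$events$gene_id,
                  LENGTH = table$events$exon_length_nt,
                  check.names = FALSE)
  for (s in colnames(table$psi)) {
    d[[s]] <- table$psi[, s]
    d[[paste0(s, ".Q")]] <- table$quality[, s]
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-tissue-group config (TSV)
#'
#' Columns `Sample`, `Group`, optional `EXCLUDED` (comma-separated target
#' groups for which the sample's group is excluded from the comparison).
#'
#' @param path TSV file path.
#' @return data.frame with columns `sample`, `group`, `excluded`.
#' @export
read_group_config <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  stopifnot(all(c("sample", "group") %in% names(d)))
  if (is.null(d$excluded)) d$excluded <- ""
  d$excluded[is.na(d$excluded)] <- ""
  d[, c("sample", "group", "excluded")]
}

#' Read a per-second activity export (CSV)
#'
#' Columns `trial`, `larva_id`, `time_s`, `activity_pct` (activity-export
#' dialect of video-tracking software).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_activity_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("larva_id", "time_s", "activity_pct") %in% names(d)))
  d
}

#' Read a per-minute per-zone export (CSV)
#'
#' Columns `trial`, `larva_id`, `minute`, `zone`, `tdm_mm`, `activity_pct`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_zone_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("larva_id", "minute", "zone", "tdm_mm", "activity_pct")
                %in% names(d)))
  d
}

#' Read a pair-trajectory CSV
#'
#' Columns `frame`, `fish_id`, `x_cm`, `y_cm`; missing coordinates blank.
#'
#' @param path CSV file path.
#' @return List of per-fish n x 2 position matrices ordered by `fish_id`.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "fish_id", "x_cm", "y_cm") %in% names(d)))
  frames <- sort(unique(d$frame))
  lapply(sort(unique(d$fish_id)), function(f) {
    df <- d[d$fish_id == f, ]
    m <- matrix(NA_real_, length(frames), 2)
    idx <- match(df$frame, frames)
    m[idx, 1] <- df$x_cm
    m[idx, 2] <- df$y_cm
    m
  })
}

#' Write a pair-trajectory CSV
#'
#' @param pair Pair object (see [gen_pair_trajectories()]).
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(pair, path) {
  n <- nrow(pair$positions[[1]])
  d <- do.call(rbind, lapply(seq_along(pair$positions), function(f) {
    data.frame(frame = seq_len(n) - 1L, fish_id = f,
               x_cm = pair$positions[[f]][, 1],
               y_cm = pair$positions[[f]][, 2])
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output GMT path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
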