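# FASTA input and BED/TSV/JSON annotation output.

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet()` that validates the
#' alphabet. Case is preserved in the returned sequences (soft-masked
#' lowercase included); decoding always uppercases. Gap characters and
#' letters outside `A,C,G,T,U,N` are rejected with the offending record and
#' position.
#'
#' @param path FASTA file path (plain text).
#' @return Tibble with columns `id` (first word of each header) and
#'   `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA: ", path)
  seqs <- as.character(set)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  for (i in seq_along(seqs)) {
    tryCatch(encode_sequence(seqs[[i]]), error = function(e) {
      stop(sprintf("record '%s': %s", ids[i], conditionMessage(e)))
    })
  }
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write repeat annotations
#'
#' Three formats:
#' * `bed`: BED6 — chrom, 0-based half-open start/end, name = canonical
#'   unit, score = region score clamped to an integer in 0..1000, strand `+`.
#' * `tsv`: human-readable table with 1-based inclusive coordinates and
#'   columns `seq`, `start`, `end`, `period`, `score`, (`pvalue`,) `unit`,
#'   `n_subrepeats`.
#' * `json`: full records including nested subrepeats (0-based half-open,
#'   as in the annotation tibble); round-trips through
#'   [read_annotations_json()].
#'
#' @param annotation Tibble from [annotate_repeats()] (sorted by sequence
#'   and start).
#' @param path Output file path or connection (`""` for stdout).
#' @param format One of `"bed"`, `"tsv"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotation, path,
                              format = c("tsv", "bed", "json")) {
  format <- match.arg(format)
  ann <- annotation[order(annotation$seq_id, annotation$start), , drop = FALSE]
  if (format == "bed") {
    df <- data.frame(
      chrom = ann$seq_id,
      start = ann$start,
      end = ann$end,
      name = ann$unit,
      score = pmax(0L, pmin(1000L, as.integer(round(ann$score)))),
      strand = rep("+", nrow(ann))
    )
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else if (format == "tsv") {
    df <- data.frame(
      seq = ann$seq_id,
      start = ann$start + 1L, # 1-based inclusive
      end = ann$end,
      period = ann$period,
      score = ann$score
    )
    if ("pvalue" %in% names(ann)) df$pvalue <- ann$pvalue
    df$unit <- ann$unit
    df$n_subrepeats <- ann$n_subrepeats
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  } else {
    recs <- lapply(seq_len(nrow(ann)), function(i) {
      r <- as.list(ann[i, setdiff(names(ann), "subrepeats")])
      r$subrepeats <- ann$subrepeats[[i]]
      r
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read annotations back from JSON
#'
#' Inverse of [write_annotations()] with `format = "json"`.
#'
#' @param path JSON file path.
#' @return Annotation tibble with a `subrepeats` list-column.
#' @export
read_annotations_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(recs, function(r) {
    subs <- dplyr::bind_rows(lapply(r$subrepeats, tibble::as_tibble))
    subs$start <- as.integer(subs$start); subs$end <- as.integer(subs$end)
    scalar <- r[setdiff(names(r), "subrepeats")]
    row <- tibble::as_tibble(scalar)
    row$subrepeats <- list(subs)
    row
  })
  out <- dplyr::bind_rows(rows)
  for (col in c("start", "end", "run_start", "period", "n_subrepeats")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  out
}

#' Write a soft-masked FASTA
#'
#' Writes the input sequences with every annotated repeat region in
#' lowercase, the conventional input to homology-search tools that ignore
#' soft-masked regions during seeding.
#'
#' @param x Sequences (as accepted by [annotate_repeats()]).
#' @param annotation Annotation tibble for those sequences.
#' @param path Output FASTA path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_softmasked_fasta <- function(x, annotation, path, width = 70L) {
  seqs <- as_sequences(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    sq <- toupper(seqs[[id]])
    regs <- annotation[annotation$seq_id == id, , drop = FALSE]
    if (nrow(regs) > 0L) {
      chars <- strsplit(sq, "")[[1]]
      for (i in seq_len(nrow(regs))) {
        span <- (regs$start[i] + 1L):regs$end[i]
        chars[span] <- tolower(chars[span])
      }
      sq <- paste(chars, collapse = "")
    }
    writeLines(paste0(">", id), con)
    starts <- seq(1L, nchar(sq), by = width)
    writeLines(substring(sq, starts, pmin(starts + width - 1L, nchar(sq))), con)
  }
  invisible(path)
}
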