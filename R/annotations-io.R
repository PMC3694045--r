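#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns a plain
#' data frame and enforces the record structure needed downstream: sequences
#' are uppercased, whitespace-stripped, and must be non-empty.
#'
#' @param path FASTA file.
#' @return data frame with columns `id` (first whitespace-delimited token of
#'   the header), `sequence`, `description` (remainder of the header, may be
#'   `""`), one row per record, in file order.  Zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      description = character(), stringsAsFactors = FALSE))
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: line ", first, " precedes any '>' header")
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  id <- sub("\\s.*$", "", headers)
  description <- trimws(sub("^\\S*\\s*", "", headers))
  sequence <- toupper(gsub("\\s", "", as.character(seqs)))
  empty <- !nzchar(sequence)
  if (any(empty))
    stop("empty sequence for record(s): ",
         paste(head(id[empty], 5L), collapse = ", "))
  data.frame(id = id, sequence = sequence, description = description,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein records to a FASTA file
#'
#' @param records data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse one subcellular-location comment
#'
#' Splits the free-text content of a `CC -!- SUBCELLULAR LOCATION` block (or
#' of one annotation-TSV cell) into (location, evidence) pairs.  A location
#' immediately followed by a parenthesised qualifier `(Probable)`,
#' `(Potential)` or `(By similarity)` -- matched case-insensitively -- gets
#' that non-experimental evidence type; a location without a qualifier is
#' taken as experimentally annotated.  A qualifier applies only to the
#' location it directly follows.
#'
#' @param text one comment string; segments are separated by `.` or `;`.
#' @param strict if `TRUE`, an unknown parenthesised qualifier is an error;
#'   otherwise it is dropped with a warning and the location is treated as
#'   experimental.
#' @return data frame with columns `location`, `evidence`.
#' @export
parse_subcellular_comment <- function(text, strict = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- sub("^\\s*SUBCELLULAR LOCATION:\\s*", "", text, ignore.case = TRUE)
  # "Note=..." free text is commentary, not a location
  text <- sub("Note=.*$", "", text, ignore.case = TRUE)
  parts <- trimws(strsplit(text, "[.;]")[[1]])
  parts <- parts[nzchar(parts)]
  qualifier_map <- c("probable" = "probable", "potential" = "potential",
                     "by similarity" = "by_similarity")
  out <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(.*?)\\s*\\(([^)]*)\\)\\s*$", p))[[1]]
    if (length(m) == 3L) {
      loc <- m[2L]
      qual <- tolower(trimws(m[3L]))
      ev <- qualifier_map[qual]
      if (is.na(ev)) {
        msg <- paste0("unknown evidence qualifier: '", m[3L], "'")
        if (strict) stop(msg)
        warning(msg, "; treating '", loc, "' as experimental")
        ev <- "experimental"
      }
    } else {
      loc <- p
      ev <- "experimental"
    }
    data.frame(location = loc, evidence = unname(ev),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(data.frame(location = character(),
                                               evidence = character()))))
  rownames(out) <- NULL
  out
}

#' Read a per-(protein, location) annotation table
#'
#' The table is tab-separated with a header and columns `accession`,
#' `location`, `evidence` (one of [evidence_types()]), one row per positive
#' (protein, location) pair; pairs absent from the table are negative.  An
#' optional logical column `fragment` flags fragment records.
#'
#' @param path TSV file.
#' @return data frame with the columns above.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "location", "evidence")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- !(tab$evidence %in% evidence_types())
  if (any(bad))
    stop("unknown evidence value(s): ",
         paste(unique(tab$evidence[bad]), collapse = ", "))
  tab
}

#' Write an annotation table
#'
#' @param annotations data frame as returned by [read_annotations()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Minimal UniProt flat-file reader
#'
#' Extracts accessions and subcellular-location comments from a Swiss-Prot
#' style flat file, reading only `AC` lines and `CC -!- SUBCELLULAR
#' LOCATION` blocks; everything else is ignored.  The first accession of
#' each entry is used.
#'
#' @param path flat file.
#' @inheritParams parse_subcellular_comment
#' @return annotation data frame (`accession`, `location`, `evidence`).
#' @export
read_uniprot_subcellular <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  acc <- NA_character_
  block <- NULL
  flush <- function() {
    if (is.null(block) || is.na(acc)) return()
    parsed <- parse_subcellular_comment(paste(block, collapse = " "),
                                        strict = strict)
    if (nrow(parsed))
      rows[[length(rows) + 1L]] <<- cbind(accession = acc, parsed)
    block <<- NULL
  }
  for (ln in lines) {
    code <- substr(ln, 1L, 2L)
    body <- trimws(substring(ln, 6L))
    if (code == "AC") {
      if (is.na(acc)) acc <- sub(";.*$", "", body)
    } else if (code == "CC") {
      if (startsWith(body, "-!-")) {
        flush()
        topic <- trimws(sub("^-!-\\s*", "", body))
        if (startsWith(toupper(topic), "SUBCELLULAR LOCATION"))
          block <- sub("^[^:]*:\\s*", "", topic)
      } else if (!is.null(block)) {
        block <- c(block, body)
      }
    } else if (code == "//") {
      flush()
      acc <- NA_character_
    } else if (code != "  ") {
      flush()
    }
  }
  flush()
  out <- do.call(rbind, c(rows, list(data.frame(accession = character(),
                                                location = character(),
                                                evidence = character()))))
  rownames(out) <- NULL
  out
}

#' Apply dataset-construction quality filters
#'
#' Discards protein fragments and sequences shorter than `min_length`
#' residues (strictly less than), keeping the input order.  A record is a
#' fragment when its description contains `"(Fragment)"` (case-insensitive).
#'
#' @param records data frame from [read_fasta()].
#' @param min_length minimum sequence length kept (default 50).
#' @param drop_fragments drop fragment records (default `TRUE`).
#' @return the filtered data frame.
#' @export
apply_quality_filters <- function(records, min_length = 50,
                                  drop_fragments = TRUE) {
  stopifnot(min_length >= 1)
  keep <- nchar(records$sequence) >= min_length
  if (drop_fragments && "description" %in% names(records))
    keep <- keep & !grepl("\\(fragment\\)", records$description,
                          ignore.case = TRUE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a labeled dataset from annotations
#'
#' Builds the `n x Q` status matrix over a fixed location vocabulary:
#' each annotation row sets its (protein, location) cell to the evidence
#' status, every unannotated cell is `"negative"`.
#'
#' @param features numeric feature matrix with rownames = accessions (e.g.
#'   from [featurize_dataset()]), or a records data frame to pass through
#'   [featurize_dataset()] with `pseaac_config()` defaults.
#' @param annotations annotation data frame ([read_annotations()]).
#' @param locations ordered character vector of the `Q` location names; an
#'   annotation naming a location outside this vocabulary is an error.
#' @return a [labeled_set()].
#' @export
build_labeled_set <- function(features, annotations, locations) {
  if (is.data.frame(features) && "sequence" %in% names(features))
    features <- featurize_dataset(features, pseaac_config())
  features <- as.matrix(features)
  ids <- rownames(features)
  if (is.null(ids)) stop("features must carry accession rownames")
  bad <- setdiff(annotations$location, locations)
  if (length(bad))
    stop("annotation location(s) outside the vocabulary: ",
         paste(bad, collapse = ", "))
  unknown <- setdiff(annotations$accession, ids)
  if (length(unknown))
    stop("annotation for unknown accession(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  status <- matrix("negative", length(ids), length(locations),
                   dimnames = list(ids, locations))
  status[cbind(annotations$accession, annotations$location)] <-
    annotations$evidence
  labeled_set(features, status, locations = locations, ids = ids)
}
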