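AMINO_ACIDS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load an amino-acid property table
#'
#' Property tables ship as plain TSV files (`residue`, `value`) so the exact
#' scale values are auditable; users may point to their own files.  The
#' three bundled scales are the hydrophobicity, hydrophilicity and
#' side-chain mass tables conventionally used with pseudo amino acid
#' composition.
#'
#' @param name one of `"hydrophobicity"`, `"hydrophilicity"`, `"mass"`, or
#'   a path to a TSV file with the same layout.
#' @return named numeric vector over the 20 canonical residues (raw scale,
#'   not yet standardized), with attribute `"property"` holding the name.
#' @export
load_property_table <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".tsv"), package = "pneaselect")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown property table: ", name)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  vals <- setNames(tab$value, tab$residue)
  missing <- setdiff(AMINO_ACIDS, names(vals))
  if (length(missing))
    stop("property table lacks residue(s): ", paste(missing, collapse = ", "))
  vals <- vals[AMINO_ACIDS]
  attr(vals, "property") <- sub("\\.tsv$", "", basename(name))
  vals
}

#' Standardize a property table to zero mean and unit spread
#'
#' Centers and scales the 20 values so their mean is 0 and their population
#' standard deviation (divisor 20) is 1, the normalization convention of
#' the series-correlation pseudo amino acid composition.
#'
#' @param raw named numeric vector over the 20 canonical residues.
#' @return the standardized vector (same names and `"property"` attribute).
#' @export
standardize_property <- function(raw) {
  if (length(raw) != 20L || !all(AMINO_ACIDS %in% names(raw)))
    stop("a property table must cover the 20 canonical residues")
  v <- as.numeric(raw[AMINO_ACIDS])
  s <- sqrt(mean((v - mean(v))^2))
  if (s < 1e-12)
    stop("constant property table: cannot standardize (zero variance)")
  out <- setNames((v - mean(v)) / s, AMINO_ACIDS)
  attr(out, "property") <- attr(raw, "property")
  out
}

#' Pseudo amino acid composition configuration
#'
#' @param properties list of property tables ([load_property_table()]);
#'   default the bundled hydrophobicity, hydrophilicity and mass scales.
#'   Tables are standardized internally.
#' @param lambda sequence-order correlation depth (number of lags, default
#'   5); `0` reduces the features to plain amino-acid composition.
#' @param weight weight factor `w >= 0` on the correlation components
#'   (default 0.4).
#' @param drop_ambiguous if `TRUE`, non-canonical residues
#'   (`B/J/O/U/X/Z`) are removed from a sequence before featurization;
#'   default `FALSE`, which rejects such sequences with an error so that
#'   feature vectors stay well-defined.
#' @return a `pseaac_config` list; feature dimension is
#'   `20 + length(properties) * lambda`.
#' @export
pseaac_config <- function(properties = default_properties(),
                          lambda = 5L, weight = 0.4,
                          drop_ambiguous = FALSE) {
  stopifnot(lambda >= 0L, weight >= 0)
  if (lambda > 0L && length(properties) == 0L)
    stop("lambda > 0 requires at least one property table")
  properties <- lapply(properties, function(p) {
    if (is.character(p) && length(p) == 1L) p <- load_property_table(p)
    standardize_property(p)
  })
  names(properties) <- vapply(properties, function(p) {
    nm <- attr(p, "property")
    if (is.null(nm)) "property" else nm
  }, character(1L))
  structure(list(properties = properties, lambda = as.integer(lambda),
                 weight = weight, drop_ambiguous = drop_ambiguous),
            class = "pneaselect_pseaac_config")
}

#' @rdname pseaac_config
#' @export
default_properties <- function() {
  lapply(c("hydrophobicity", "hydrophilicity", "mass"), load_property_table)
}

clean_sequence <- function(sequence, config) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad <- !(chars %in% AMINO_ACIDS)
  if (any(bad)) {
    if (config$drop_ambiguous) chars <- chars[!bad]
    else stop("non-canonical residue(s) ",
              paste(unique(chars[bad]), collapse = ""),
              " in sequence; set drop_ambiguous = TRUE to remove them")
  }
  chars
}

#' Amphiphilic pseudo amino acid composition of one sequence
#'
#' The feature vector has `20 + m * lambda` components for `m` property
#' scales.  The first 20 are amino-acid occurrence frequencies; component
#' `20 + (p-1)*lambda + j` is `w * tau_pj`, where `tau_pj` is the mean over
#' all residue pairs at lag `j` of the product of standardized property-`p`
#' values.  All components share the normalizer `1 + w * sum(tau)`, so the
#' vector sums to 1.
#'
#' @param sequence amino-acid string of length `L > lambda`.
#' @param config a [pseaac_config()].
#' @return named numeric vector of length `20 + m * lambda`.
#' @export
pseaac_vector <- function(sequence, config = pseaac_config()) {
  chars <- clean_sequence(sequence, config)
  L <- length(chars)
  lam <- config$lambda
  if (L <= lam)
    stop("sequence length ", L, " must exceed lambda = ", lam)
  comp <- tabulate(match(chars, AMINO_ACIDS), nbins = 20L) / L
  m <- length(config$properties)
  tau <- numeric(m * lam)
  if (lam > 0L) {
    prop_vals <- lapply(config$properties, function(p) unname(p[chars]))
    for (p in seq_len(m)) {
      h <- prop_vals[[p]]
      for (j in seq_len(lam)) {
        tau[(p - 1L) * lam + j] <-
          mean(h[seq_len(L - j)] * h[seq_len(L - j) + j])
      }
    }
  }
  w <- config$weight
  denom <- 1 + w * sum(tau)
  if (denom <= 1e-9)
    stop("non-positive pseudo-composition normalizer (", signif(denom, 4),
         "); the correlation terms overwhelm the composition mass -- ",
         "reduce weight or lambda")
  out <- c(comp, w * tau) / denom
  names(out) <- pseaac_names(config)
  out
}

pseaac_names <- function(config) {
  lam <- config$lambda
  corr <- if (lam > 0L)
    as.vector(t(outer(names(config$properties), seq_len(lam),
                      function(p, j) paste0(p, ".lag", j))))
  else character()
  c(AMINO_ACIDS, corr)
}

#' Featurize a set of protein records
#'
#' @param records data frame with columns `id` and `sequence`
#'   (e.g. from [read_fasta()]).
#' @param config a [pseaac_config()].
#' @return numeric `n x d` matrix, rownames = record ids, one row per
#'   record in input order.
#' @export
featurize_dataset <- function(records, config = pseaac_config()) {
  d <- 20L + length(config$properties) * config$lambda
  out <- matrix(0, nrow(records), d,
                dimnames = list(records$id, pseaac_names(config)))
  for (i in seq_len(nrow(records))) {
    row <- tryCatch(pseaac_vector(records$sequence[i], config),
                    error = function(e)
                      stop("record '", records$id[i], "': ",
                           conditionMessage(e), call. = FALSE))
    out[i, ] <- row
  }
  out
}
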