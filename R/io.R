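# Flat-file readers for the five input tables and the complex-set formats.
# All inputs are tab-separated, '#' starts a comment line, malformed rows
# raise an error naming the offending line.

.read_tsv <- function(path, col_names, numeric_cols = integer(0)) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(col_names)),
                                  col_names), stringsAsFactors = FALSE)
    for (j in numeric_cols) out[[j]] <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < length(col_names))
  if (length(bad)) {
    stop(sprintf("parse error in '%s' at line %d: expected %d tab-separated fields, found %d",
                 path, keep[bad[1]], length(col_names), lengths(parts)[bad[1]]))
  }
  out <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
    trimws(p[seq_along(col_names)])
  })), stringsAsFactors = FALSE)
  names(out) <- col_names
  for (j in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    if (anyNA(v)) {
      bad_row <- which(is.na(v))[1]
      stop(sprintf("parse error in '%s' at line %d: '%s' is not a number",
                   path, keep[bad_row], out[[j]][bad_row]))
    }
    out[[j]] <- v
  }
  out
}

#' Read the tab-separated input tables
#'
#' `read_ppi` reads an undirected protein-protein interaction edge list
#' (columns `protein_a`, `protein_b`); `read_domains` a protein-to-domain
#' table with one row per slot occurrence (`protein`, `domain`);
#' `read_ddi` an undirected domain-domain interaction list (`domain_a`,
#' `domain_b`); `read_abundance` a copy-number table (`protein`,
#' `copies_per_cell`); `read_annotations` a functional annotation table
#' (`protein`, `term`); `read_drug_targets` a drug-target list (`drug_id`,
#' `target_protein`). Lines starting with `#` are comments.
#'
#' @param path Path to the tab-separated file.
#' @return A data frame with the columns named above.
#' @export
read_ppi <- function(path) .read_tsv(path, c("protein_a", "protein_b"))

#' @rdname read_ppi
#' @export
read_domains <- function(path) .read_tsv(path, c("protein", "domain"))

#' @rdname read_ppi
#' @export
read_ddi <- function(path) .read_tsv(path, c("domain_a", "domain_b"))

#' @rdname read_ppi
#' @export
read_abundance <- function(path) {
  .read_tsv(path, c("protein", "copies_per_cell"), numeric_cols = 2L)
}

#' @rdname read_ppi
#' @export
read_annotations <- function(path) .read_tsv(path, c("protein", "term"))

#' @rdname read_ppi
#' @export
read_drug_targets <- function(path) .read_tsv(path, c("drug_id", "target_protein"))

#' Read a reference complex set
#'
#' One complex per line, tab-separated member identifiers; `#` comments.
#'
#' @param path File path.
#' @param source Optional label recorded on the returned set.
#' @return A list of character vectors of member identifiers, with
#'   attribute `source`.
#' @export
read_reference_complexes <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  keep <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- lapply(strsplit(keep, "\t", fixed = TRUE), function(p) {
    unique(trimws(p[nzchar(trimws(p))]))
  })
  attr(out, "source") <- source
  out
}

#' Write a complex set in the reference format
#'
#' @param complexes List of character vectors of member identifiers.
#' @param path Output path.
#' @export
write_reference_complexes <- function(complexes, path) {
  writeLines(vapply(complexes, function(m) paste(sort(m), collapse = "\t"),
                    character(1)), path)
  invisible(path)
}

#' Write / read simulated complexes as TSV
#'
#' Columns: `run_id`, `sample_time`, `members` (semicolon-joined, sorted,
#' multiplicities retained), `bonds` (semicolon-joined `pA:dA-pB:dB`) and
#' `fictitious_fraction`.
#'
#' @param scs A list of simulated-complex records (see [run_simulation()]).
#' @param path File path.
#' @export
write_scs <- function(scs, path) {
  if (inherits(scs, "sc_sim")) scs <- scs$scs
  rows <- vapply(scs, function(sc) {
    b <- sc$bonds
    bond_str <- if (!is.null(b) && nrow(b)) {
      paste(sprintf("%s:%s-%s:%s", b$protein_a, b$domain_a,
                    b$protein_b, b$domain_b), collapse = ";")
    } else ""
    paste(sc$run_id, sc$sample_time,
          paste(sort(sc$members), collapse = ";"),
          bond_str,
          format(sc$fictitious_fraction, digits = 6),
          sep = "\t")
  }, character(1))
  writeLines(c("run_id\tsample_time\tmembers\tbonds\tfictitious_fraction", rows),
             path)
  invisible(path)
}

#' @rdname write_scs
#' @export
read_scs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    bonds <- NULL
    if (nzchar(df$bonds[i])) {
      ends <- strsplit(strsplit(df$bonds[i], ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
      pa <- vapply(ends, function(e) strsplit(e[1], ":", fixed = TRUE)[[1]], character(2))
      pb <- vapply(ends, function(e) strsplit(e[2], ":", fixed = TRUE)[[1]], character(2))
      bonds <- data.frame(protein_a = pa[1, ], domain_a = pa[2, ],
                          protein_b = pb[1, ], domain_b = pb[2, ],
                          fictitious = NA, stringsAsFactors = FALSE)
    }
    list(members = strsplit(df$members[i], ";", fixed = TRUE)[[1]],
         bonds = bonds,
         run_id = df$run_id[i],
         sample_time = df$sample_time[i],
         fictitious_fraction = df$fictitious_fraction[i])
  })
}
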