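# Drug (SMILES) and protein (FASTA) record IO.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read drug records (id + SMILES)
#'
#' Accepts either a plain SMILES file with one `id<TAB>smiles` per line, or a
#' CSV with columns `id` and `smiles` (detected from the header line). SMILES
#' validity is checked lazily at featurization, not here.
#'
#' @param path Input file.
#' @return A `data.frame` with character columns `id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path))
    fdta_stop(sprintf("no such file: %s", path), "fusedta_io_error")
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE) && grepl("smiles", first, ignore.case = TRUE)) {
    df <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    for (col in c("id", "smiles"))
      if (!col %in% names(df))
        fdta_stop(sprintf("missing required column '%s' in %s", col, path),
                  "fusedta_format_error")
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L))
      fdta_stop(sprintf("line %d of %s is not 'id<TAB>smiles'",
                        which(lengths(parts) < 2L)[1L], path),
                "fusedta_format_error")
    df <- data.frame(id = vapply(parts, `[`, "", 1L),
                     smiles = vapply(parts, `[`, "", 2L),
                     stringsAsFactors = FALSE)
  }
  if (any(!nzchar(df$smiles)))
    fdta_stop("empty SMILES string in input", "fusedta_format_error")
  if (anyDuplicated(df$id))
    fdta_stop(sprintf("duplicate drug id '%s'", df$id[duplicated(df$id)][1L]),
              "fusedta_duplicate_error")
  df[c("id", "smiles")]
}

#' Write drug records as a tab-separated SMILES file
#' @param drugs `data.frame` with columns `id`, `smiles`.
#' @param path Output path.
#' @export
write_smiles_file <- function(drugs, path) {
  writeLines(paste(drugs$id, drugs$smiles, sep = "\t"), path)
  invisible(path)
}

#' Read protein records from FASTA
#'
#' Record ids are taken from the FASTA header up to the first whitespace.
#' Sequences are uppercased and must use the 20-letter amino-acid alphabet
#' plus `X` for unknown residues.
#'
#' @param path FASTA file.
#' @return A `data.frame` with character columns `id` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path))
    fdta_stop(sprintf("no such file: %s", path), "fusedta_io_error")
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad))
    fdta_stop(sprintf("protein '%s' contains characters outside the amino-acid alphabet",
                      ids[bad][1L]),
              "fusedta_format_error")
  if (any(!nzchar(seqs)))
    fdta_stop("empty protein sequence in FASTA", "fusedta_format_error")
  if (anyDuplicated(ids))
    fdta_stop(sprintf("duplicate protein id '%s'", ids[duplicated(ids)][1L]),
              "fusedta_duplicate_error")
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#' @param proteins `data.frame` with columns `id`, `sequence`.
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
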