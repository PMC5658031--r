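# PDB and FASTA input/output for backbone structures.

#' Read a backbone structure from a PDB file
#'
#' Parses ATOM records (via [bio3d::read.pdb]) and keeps the four backbone
#' atoms N, CA, C, O of each residue.  Only the first model of a multi-model
#' file is used; alternate locations resolve to the first occurrence.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier; default uses all chains in file
#'   order.
#' @param strict If `TRUE` (default) a residue missing any of the four
#'   backbone atoms is an error; if `FALSE` such residues are dropped with a
#'   message.
#' @return A [backbone_structure()].
#' @export
read_pdb <- function(path, chain = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no parsable residues in '", path, "'")
  # first altloc occurrence per (chain, residue, atom)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  at <- at[!duplicated(key), , drop = FALSE]

  reskey <- paste(at$chain, at$resno, at$insert, sep = "|")
  reskey <- factor(reskey, levels = unique(reskey))  # preserve file order
  keep <- logical(nlevels(reskey))
  seqs <- character(0); blocks <- list()
  for (i in seq_len(nlevels(reskey))) {
    r <- at[reskey == levels(reskey)[i], , drop = FALSE]
    if (!all(BACKBONE_ATOMS %in% r$elety)) {
      if (strict) stop("residue ", levels(reskey)[i],
                       " is missing a backbone atom (strict mode)")
      message("read_pdb: dropping residue ", levels(reskey)[i],
              " with incomplete backbone")
      next
    }
    r <- r[match(BACKBONE_ATOMS, r$elety), , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- cbind(r$x, r$y, r$z)
    aa <- suppressWarnings(bio3d::aa321(r$resid[1]))
    seqs <- c(seqs, if (is.na(aa)) "X" else aa)
  }
  if (length(blocks) < 2) stop("no parsable residues in '", path,
                               "' (need >= 2 complete backbone residues)")
  backbone_structure(seqs, do.call(rbind, blocks),
                     id = sub("\\.pdb$", "", basename(path)))
}

#' Write a backbone structure to a PDB file
#'
#' Emits standard fixed-column ATOM records (serial from 1, chain A,
#' occupancy 1.00, B-factor 0.00, element symbol filled), followed by TER and
#' END.
#'
#' @param structure A [backbone_structure()] with coordinates in Angstrom.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  validate_backbone(structure)
  if (any(abs(structure$coords) >= 10000))
    stop("coordinate outside the fixed-width PDB field range (|value| >= 10000 A)")
  L <- n_residues(structure)
  res3 <- vapply(structure$sequence, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r) || !nzchar(r)) "UNK" else r
  }, character(1))
  lines <- character(4 * L + 2)
  serial <- 0L
  for (i in seq_len(L)) {
    for (j in seq_len(4)) {
      serial <- serial + 1L
      atom <- BACKBONE_ATOMS[j]
      xyz <- structure$coords[i, j, ]
      fld <- sprintf("%8.3f%8.3f%8.3f", xyz[1], xyz[2], xyz[3])
      if (nchar(fld) != 24)
        stop("coordinate outside the fixed-width PDB field range (|value| >= 10000 A)")
      lines[serial] <- sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %s%6.2f%6.2f          %2s",
        serial, atom, res3[i], i, fld, 1.00, 0.00, substr(atom, 1, 1))
    }
  }
  lines[4 * L + 1] <- sprintf("TER   %5d      %3s A%4d", serial + 1L, res3[L], L)
  lines[4 * L + 2] <- "END"
  writeLines(lines, path)
  invisible(path)
}

#' Read a target amino-acid sequence
#'
#' Accepts either a FASTA file path or a plain one-letter sequence string.
#'
#' @param x FASTA path or sequence string.
#' @return Character vector of one-letter codes.
#' @export
read_sequence <- function(x) {
  if (length(x) == 1 && file.exists(x)) {
    fa <- bio3d::read.fasta(x)
    s <- fa$ali[1, ]
    s <- s[!s %in% c("-", ".")]
    return(toupper(unname(s)))
  }
  split_sequence(x)
}
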