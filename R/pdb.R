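#' Parse fatty-acid (or any) ligand conformers from PDB-format text
#'
#' Extracts one conformer per (model, chain, residue number, insertion code)
#' carrying the requested 3-letter residue code from ATOM/HETATM records.
#' Alternate locations are resolved per atom name to the highest occupancy;
#' ties go to the lexicographically first altloc identifier. Elements come
#' from columns 77-78, falling back to the leading letter of the atom name.
#'
#' @param pdb_text character: either one string with embedded newlines or a
#'   vector of lines.
#' @param code 3-letter residue name to extract (e.g. \code{"PLM"},
#'   \code{"PAM"}).
#' @param source_id identifier stamped on the extracted conformers
#'   (typically the file name); residue selectors are appended.
#' @return list of \code{ligand_conformer} objects (empty when no residue
#'   matches).
#' @seealso [read_ligands()] for files, [superpose_carbons()],
#'   [rmsd_density()].
#' @export
parse_ligands <- function(pdb_text, code, source_id = "pdb") {
  stopifnot(is.character(pdb_text), nchar(code) >= 1)
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  rec <- substr(lines, 1, 6)
  model <- cumsum(rec == "MODEL ")
  keep <- which((rec == "HETATM" | rec == "ATOM  ") &
                  trimws(substr(lines, 18, 20)) == toupper(code))
  if (length(keep) == 0L) return(list())
  fld <- function(lo, hi) substr(lines[keep], lo, hi)
  coords <- suppressWarnings(cbind(as.numeric(fld(31, 38)),
                                   as.numeric(fld(39, 46)),
                                   as.numeric(fld(47, 54))))
  bad <- which(!complete.cases(coords))
  if (length(bad))
    stop(sprintf("malformed coordinate fields at line %d: %s",
                 keep[bad[1]], lines[keep[bad[1]]]), call. = FALSE)
  occ <- suppressWarnings(as.numeric(fld(55, 60)))
  occ[is.na(occ)] <- 1
  name <- trimws(fld(13, 16))
  elem <- trimws(fld(77, 78))
  fallback <- toupper(substr(gsub("[^A-Za-z].*$", "", name), 1, 1))
  elem <- ifelse(elem == "", fallback, toupper(elem))
  atoms <- data.frame(name = name, element = elem,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      altloc = substr(lines[keep], 17, 17),
                      occupancy = occ,
                      chain = substr(lines[keep], 22, 22),
                      res_seq = suppressWarnings(
                        as.integer(trimws(fld(23, 26)))),
                      icode = substr(lines[keep], 27, 27),
                      model = model[keep], stringsAsFactors = FALSE)
  if (anyNA(atoms$res_seq))
    stop(sprintf("malformed residue number at line %d",
                 keep[which(is.na(atoms$res_seq))[1]]), call. = FALSE)
  grp <- interaction(atoms$model, atoms$chain, atoms$res_seq, atoms$icode,
                     drop = TRUE)
  out <- lapply(split(atoms, grp), function(res) {
    # altloc resolution: per atom name keep highest occupancy, ties ->
    # lexicographically first altloc (' ' sorts before 'A')
    res <- res[order(res$name, -res$occupancy, res$altloc), , drop = FALSE]
    res <- res[!duplicated(res$name), , drop = FALSE]
    # restore file order of atoms (by original row)
    res <- res[order(as.integer(rownames(res))), , drop = FALSE]
    sid <- sprintf("%s:%s%s%d%s", source_id,
                   if (max(atoms$model) > 0) paste0("m", res$model[1], ":")
                   else "",
                   res$chain[1], res$res_seq[1], trimws(res$icode[1]))
    new_ligand_conformer(
      source_id = sid, ligand_code = toupper(code), chain = res$chain[1],
      res_seq = res$res_seq[1],
      atoms = data.frame(name = res$name, element = res$element,
                         x = res$x, y = res$y, z = res$z,
                         altloc = trimws(res$altloc),
                         occupancy = res$occupancy,
                         stringsAsFactors = FALSE))
  })
  unname(out)
}

#' Read ligand conformers from PDB files
#'
#' @param paths character vector of PDB-format file paths.
#' @param code 3-letter residue name to extract.
#' @return list of \code{ligand_conformer}, concatenated over files;
#'   \code{source_id} is \code{<file>:<chain><resseq>}.
#' @export
read_ligands <- function(paths, code) {
  out <- list()
  for (p in paths) {
    lig <- parse_ligands(readLines(p, warn = FALSE), code,
                         source_id = basename(p))
    out <- c(out, lig)
  }
  out
}
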