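## Reading, writing and constructing ComplexStructure objects.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
.DNA <- c("DA", "DC", "DG", "DT")
.RNA <- c("A", "C", "G", "U")

aaThreeToOne <- function(res) {
  i <- match(res, .AA3)
  out <- .AA1[i]
  out[is.na(i)] <- "X"
  out
}

.entityTypeOfResidues <- function(res_names) {
  if (all(res_names %in% .AA3)) "protein"
  else if (all(res_names %in% .DNA)) "dna"
  else if (all(res_names %in% .RNA)) "rna"
  else "nonpolymer"
}

.chainSequence <- function(res_names, entity_type) {
  switch(entity_type,
         protein = paste(aaThreeToOne(res_names), collapse = ""),
         dna = paste(sub("^D", "", res_names), collapse = ""),
         rna = paste(res_names, collapse = ""),
         nonpolymer = paste(res_names, collapse = ","))
}

#' Construct a ComplexStructure
#'
#' Builds the container from an atom table, deriving chain metadata,
#' element radii and heavy-atom flags when not supplied.  Chains sharing an
#' entity type and polymer sequence (or residue composition, for
#' non-polymers) are assigned the same \code{entity_id} and thereby marked
#' as symmetric copies.
#'
#' @param atoms data.frame; required columns \code{atom_name},
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{chain_id},
#'   \code{res_idx}, \code{res_name}.  Optional: \code{atom_id},
#'   \code{is_resolved}, \code{is_heavy}, \code{vdw_radius}.
#' @param bonds data.frame with columns \code{i}, \code{j} (atom row
#'   indices); may be NULL.
#' @param entity_types optional named character vector chain_id -> entity
#'   type, overriding residue-name inference.
#' @return a \linkS4class{ComplexStructure}
#' @export
complexStructure <- function(atoms, bonds = NULL, entity_types = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$is_resolved)) atoms$is_resolved <- TRUE
  if (is.null(atoms$is_heavy))
    atoms$is_heavy <- atoms$element != "H"
  if (is.null(atoms$vdw_radius))
    atoms$vdw_radius <- vdwRadius(atoms$element)
  if (is.null(atoms$atom_id))
    atoms$atom_id <- paste(atoms$chain_id, atoms$res_idx, atoms$atom_name,
                           sep = ":")
  atoms$res_idx <- as.integer(atoms$res_idx)
  bad <- !grepl("^[A-Za-z]{1,2}$", atoms$element)
  if (any(bad))
    stop("unknown element symbol for atom(s): ",
         paste(utils::head(atoms$atom_id[bad], 5), collapse = ", "))

  cid <- unique(atoms$chain_id)
  ct <- character(length(cid)); sq <- character(length(cid))
  for (k in seq_along(cid)) {
    sub <- atoms[atoms$chain_id == cid[k], ]
    rn <- sub$res_name[!duplicated(sub$res_idx)]
    ct[k] <- if (!is.null(entity_types) && cid[k] %in% names(entity_types))
      entity_types[[cid[k]]] else .entityTypeOfResidues(rn)
    sq[k] <- .chainSequence(rn, ct[k])
  }
  key <- paste(ct, sq, sep = "|")
  eid <- paste0("E", as.integer(factor(key, levels = unique(key))))
  chains <- data.frame(chain_id = cid, entity_type = ct, sequence = sq,
                       entity_id = eid, stringsAsFactors = FALSE)

  if (is.null(bonds))
    bonds <- data.frame(i = integer(0), j = integer(0),
                        inter_chain = logical(0))
  bonds <- as.data.frame(bonds)
  if (nrow(bonds))
    bonds$inter_chain <- atoms$chain_id[bonds$i] != atoms$chain_id[bonds$j]
  else bonds$inter_chain <- logical(0)

  new("ComplexStructure", atoms = atoms, chains = chains, bonds = bonds)
}

#' Read a structure file
#'
#' Parses a PDB or mmCIF file (via bio3d) into a
#' \linkS4class{ComplexStructure}.  All atoms present in the file are taken
#' as resolved; alternate locations beyond the first are dropped.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @param entity_types optional named chain_id -> entity type overrides.
#' @return a \linkS4class{ComplexStructure}
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                           entity_types = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif"
              else "pdb"
  parsed <- withCallingHandlers(
    tryCatch(
      if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
      else bio3d::read.cif(path, verbose = FALSE),
      error = function(e) stop("failed to parse ", format, " file '", path,
                               "': ", conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      # bio3d tags its cif reader as beta on every call
      if (grepl("beta version|helix/sheet", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  at <- parsed$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A", "1"), , drop = FALSE]
  if (!nrow(at)) stop("no atom records in ", path)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- sub("^([A-Za-z]).*", "\\1", trimws(at$elety))
  }
  elem <- trimws(elem)
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 10)))
  atoms <- data.frame(atom_name = trimws(at$elety), element = elem,
                      x = at$x, y = at$y, z = at$z,
                      chain_id = as.character(at$chain),
                      res_idx = as.integer(at$resno),
                      res_name = trimws(at$resid),
                      stringsAsFactors = FALSE)
  complexStructure(atoms, entity_types = entity_types)
}

#' Write a structure file
#'
#' Writes the resolved atoms of a complex as PDB (via bio3d) or as a
#' minimal mmCIF \code{atom_site} loop.  Coordinates are written with
#' 3-decimal precision in both formats.
#'
#' @param x a \linkS4class{ComplexStructure}
#' @param path output path
#' @param format \code{"auto"}, \code{"pdb"} or \code{"mmcif"}
#' @return \code{path}, invisibly
#' @export
writeStructure <- function(x, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif"
              else "pdb"
  a <- atoms(x)[atoms(x)$is_resolved, , drop = FALSE]
  het <- x@chains$entity_type[match(a$chain_id, x@chains$chain_id)] ==
    "nonpolymer"
  if (format == "pdb") {
    xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz, type = ifelse(het, "HETATM",
                     "ATOM"), resno = a$res_idx, resid = a$res_name,
                     chain = a$chain_id, elety = a$atom_name,
                     eleno = seq_len(nrow(a)), elesy = toupper(a$element))
  } else {
    ent <- match(a$chain_id, x@chains$chain_id)
    lines <- c(
      "data_steerkit", "#", "loop_",
      paste0("_atom_site.",
             c("group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
               "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
               "auth_comp_id", "auth_asym_id", "auth_atom_id",
               "pdbx_PDB_model_num")),
      sprintf(paste("%-6s %5d %-2s %-4s . %-4s %-2s %d %d ?",
                    "%8.3f %8.3f %8.3f %4.2f %5.2f ? %d %-4s %-2s %-4s 1"),
              ifelse(het, "HETATM", "ATOM"), seq_len(nrow(a)),
              toupper(a$element), a$atom_name, a$res_name, a$chain_id,
              ent, a$res_idx, a$x, a$y, a$z, 1, 0, a$res_idx,
              a$res_name, a$chain_id, a$atom_name),
      "#")
    writeLines(lines, path)
  }
  invisible(path)
}
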