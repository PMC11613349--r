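# PDB input/output for mimetic structures.  ATOM records go through bio3d;
# CONECT records (the distribution format's bond graph, which bio3d does
# not handle) are parsed and emitted here.  Atom serials start at 1 with
# the preceding-residue C' first.

#' Write a mimetic structure as PDB with CONECT records
#'
#' Three residues are emitted: the cap carbonyl (residue 1), the central
#' residue, and the cap amide (residue 3).  The first serial is the
#' preceding C'.  Every covalent bond appears in the CONECT block.
#'
#' @param structure a [build_mimetic()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mimetic <- function(structure, path) {
  at <- structure$atoms
  resid <- ifelse(at$resno == 2L, structure$residue, "GLY")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  bio3d::write.pdb(file = tmp,
                   xyz = as.vector(t(structure$xyz)),
                   resno = at$resno, resid = resid,
                   eleno = seq_len(nrow(at)), elety = at$name,
                   elesy = at$element, chain = "A")
  lines <- readLines(tmp)
  lines <- lines[!grepl("^END", lines)]
  nbr <- lapply(seq_len(nrow(at)), function(i) {
    sort(unique(c(structure$bonds[structure$bonds[, 1L] == i, 2L],
                  structure$bonds[structure$bonds[, 2L] == i, 1L])))
  })
  conect <- vapply(seq_along(nbr), function(i) {
    paste0("CONECT", paste0(sprintf("%5d", c(i, nbr[[i]])), collapse = ""))
  }, character(1L))
  writeLines(c(lines, conect, "END"), path)
  invisible(path)
}

#' Read a mimetic structure from PDB with CONECT records
#'
#' Atoms and coordinates come from the ATOM records (via bio3d); the
#' covalent-bond graph comes from the CONECT records, which are mandatory.
#' Roles are inferred from residue position (first/last residue = cap) and
#' atom naming; torsion definitions are attached from the standard
#' phi/psi/chi atom paths for the central residue.
#'
#' @param path PDB file with CONECT records.
#' @param geometry geometry configuration supplying the chi torsion
#'   definitions (see [default_geometry()]).
#' @return a `mimetic` object.
#' @export
read_mimetic <- function(path, geometry = default_geometry()) {
  raw <- readLines(path)
  conect_lines <- grep("^CONECT", raw, value = TRUE)
  if (length(conect_lines) == 0L) {
    stop("PDB file has no CONECT records; the covalent bond graph is ",
         "required", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  resnos <- sort(unique(at$resno))
  if (length(resnos) != 3L) {
    stop("expected a three-residue mimetic (cap / residue / cap), found ",
         length(resnos), " residues", call. = FALSE)
  }
  central <- resnos[2L]
  residue <- unique(at$resid[at$resno == central])[1L]
  if (!residue %in% names(geometry$residues)) {
    stop("unknown central residue '", residue, "'", call. = FALSE)
  }
  element <- at$elesy
  if (is.null(element) || !all(nzchar(element))) {
    element <- substr(gsub("[^A-Za-z].*", "", at$elety), 1L, 1L)
  }
  role <- ifelse(at$resno != central, "cap",
          ifelse(at$elety %in% c("N", "H", "CA", "HA", "C", "O"),
                 "backbone", "sidechain"))
  id <- at$elety
  id[at$resno == resnos[1L] & at$elety == "C"] <- "C0"
  id[at$resno == resnos[1L] & at$elety == "O"] <- "O0"
  id[at$resno == resnos[3L] & at$elety == "N"] <- "N2"
  id[at$resno == resnos[3L] & at$elety == "H"] <- "H2"
  atoms <- tibble::tibble(id = id, name = at$elety, element = element,
                          role = role,
                          resno = match(at$resno, resnos))
  xyz <- cbind(at$x, at$y, at$z)

  serial_map <- match(as.integer(substr(conect_lines, 7L, 11L)), at$eleno)
  bonds <- NULL
  for (k in seq_along(conect_lines)) {
    ln <- conect_lines[k]
    from <- serial_map[k]
    pos <- 12L
    while (pos + 4L <= nchar(ln)) {
      to <- match(as.integer(substr(ln, pos, pos + 4L)), at$eleno)
      if (!is.na(to) && !is.na(from) && from != to) {
        bonds <- rbind(bonds, sort(c(from, to)))
      }
      pos <- pos + 5L
    }
  }
  bonds <- unique(bonds)

  spec <- geometry$residues[[residue]]
  torsion_defs <- c(
    list(phi = c("C0", "N", "CA", "C"), psi = c("N", "CA", "C", "N2")),
    stats::setNames(lapply(spec$chis, function(ch) unlist(ch$atoms)),
                    vapply(spec$chis, function(ch) ch$name, character(1L)))
  )
  st <- new_mimetic(residue, atoms, xyz, bonds, torsion_defs,
                    backbone_angle = NA_real_)
  idx <- match(c("N", "CA", "C"), atoms$id)
  st$backbone_angle <- angle3(xyz[idx[1L], ], xyz[idx[2L], ], xyz[idx[3L], ])
  st
}
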