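# Atomic model I/O and conversion to the Gaussian-mixture representation.
# PDB files go through bio3d; mmCIF reading is a minimal atom_site parser;
# hydrogens are never part of the model (they are a deterministic overlay).

ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)
WATER_RES <- c("HOH", "WAT", "DOD")

#' Construct an atomic model
#'
#' @param atoms data frame with columns `atom`, `element`, `res_name`,
#'   `res_seq`, `ins`, `chain`, `occ`
#' @param xyz N x 3 coordinate matrix (Angstrom)
#' @return object of class `atomic_model`
#' @export
atomic_model <- function(atoms, xyz) {
  stopifnot(nrow(atoms) == nrow(xyz), all(is.finite(xyz)))
  xyz <- unname(as.matrix(xyz))
  chains <- unique(atoms$chain)
  ctype <- vapply(chains, function(ch) {
    rn <- unique(atoms$res_name[atoms$chain == ch])
    if (any(rn %in% NT1)) "rna" else "protein"
  }, "")
  structure(list(atoms = atoms, xyz = xyz,
                 chain_types = stats::setNames(ctype, chains)),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  rid <- residue_ids(x)
  cat("atomic_model:", nrow(x$atoms), "atoms,", length(unique(rid)),
      "residues,", length(x$chain_types), "chain(s) [",
      paste(paste0(names(x$chain_types), ":", x$chain_types), collapse = " "),
      "]\n")
  invisible(x)
}

element_from_name <- function(nm) {
  e <- toupper(substr(gsub("^[0-9']+", "", nm), 1, 1))
  ifelse(e %in% names(ATOMIC_NUMBER), e, "C")
}

#' Read an atomic model from PDB or mmCIF
#'
#' Hydrogens and waters are stripped, alternate locations are collapsed to
#' the highest-occupancy conformer, and chain types are inferred from
#' residue names.
#'
#' @param path file path; format chosen by extension (`.pdb` vs
#'   `.cif`/`.mmcif`)
#' @return an [atomic_model()]
#' @export
read_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) df <- read_mmcif_atoms(path)
  else {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop("cannot parse PDB file '", path,
                                             "': ", conditionMessage(e)))
    a <- pdb$atom
    df <- data.frame(atom = trimws(a$elety),
                     element = trimws(a$elesy),
                     res_name = trimws(a$resid),
                     res_seq = a$resno,
                     ins = ifelse(is.na(a$insert) | a$insert == "", "",
                                  a$insert),
                     chain = ifelse(is.na(a$chain), "A", a$chain),
                     alt = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
                     occ = ifelse(is.na(a$o), 1, a$o),
                     x = a$x, y = a$y, z = a$z,
                     stringsAsFactors = FALSE)
  }
  df$element[df$element == "" | is.na(df$element)] <-
    element_from_name(df$atom[df$element == "" | is.na(df$element)])
  df <- df[df$element != "H" & df$element != "D", ]
  df <- df[!(df$res_name %in% WATER_RES), ]
  # collapse altlocs: keep the highest-occupancy conformer per atom site
  if (any(df$alt != "")) {
    site <- paste(df$chain, df$res_seq, df$ins, df$atom)
    keep <- unlist(lapply(split(seq_len(nrow(df)), site), function(i) {
      i[which.max(df$occ[i])]
    }), use.names = FALSE)
    df <- df[sort(keep), ]
  }
  # normalise nucleotide residue names (RA/RG style -> A/G)
  df$res_name <- sub("^R([ACGU])$", "\\1", df$res_name)
  atomic_model(df[, c("atom", "element", "res_name", "res_seq", "ins",
                      "chain", "occ")],
               as.matrix(df[, c("x", "y", "z")]))
}

# minimal mmCIF atom_site reader (loop_ records only)
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  li <- grep("^_atom_site\\.", lines)
  if (!length(li)) stop("no _atom_site loop in mmCIF file '", path, "'")
  fields <- sub("^_atom_site\\.", "", trimws(lines[li]))
  body_start <- max(li) + 1
  body <- character(0)
  for (i in body_start:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || startsWith(l, "#") || startsWith(l, "loop_") ||
        startsWith(l, "_")) break
    body <- c(body, l)
  }
  tok <- strsplit(body, "[[:space:]]+")
  bad <- which(lengths(tok) != length(fields))
  if (length(bad))
    stop("malformed mmCIF atom_site record at data row ", bad[1],
         " of '", path, "'")
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  gv <- function(nm, alt = NULL, default = NA) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else rep(default, nrow(m))
  }
  ins <- gv("pdbx_PDB_ins_code", default = "")
  ins[ins %in% c("?", ".")] <- ""
  data.frame(atom = gsub('"', "", gv("label_atom_id")),
             element = gv("type_symbol", default = ""),
             res_name = gv("label_comp_id"),
             res_seq = as.integer(gv("auth_seq_id", "label_seq_id")),
             ins = ins,
             chain = gv("auth_asym_id", "label_asym_id", "A"),
             alt = ifelse(gv("label_alt_id", default = ".") %in% c(".", "?"),
                          "", gv("label_alt_id", default = ".")),
             occ = as.numeric(gv("occupancy", default = "1")),
             x = as.numeric(gv("Cartn_x")),
             y = as.numeric(gv("Cartn_y")),
             z = as.numeric(gv("Cartn_z")),
             stringsAsFactors = FALSE)
}

#' Convert a model to its Gaussian-mixture representation
#'
#' One isotropic 3D Gaussian per (non-hydrogen) atom: centers are the atom
#' coordinates, amplitudes are proportional to the atomic number, and a
#' single shared width is set from the target resolution.
#'
#' @param model an `atomic_model`
#' @param resolution target resolution in Angstrom (sets the width)
#' @param width optional explicit width (Angstrom), overrides `resolution`
#' @param amplitude_policy `"atomic_number"` or `"uniform"`
#' @return object of class `gaussian_mixture` with `centers`, `amplitudes`,
#'   `width`
#' @export
model_to_gmm <- function(model, resolution = 8,
                         width = NULL,
                         amplitude_policy = c("atomic_number", "uniform")) {
  amplitude_policy <- match.arg(amplitude_policy)
  if (is.null(width)) width <- sigma_from_resolution(resolution)
  amp <- if (amplitude_policy == "atomic_number") {
    z <- ATOMIC_NUMBER[model$atoms$element]
    z[is.na(z)] <- 6
    unname(z) / 6
  } else rep(1, nrow(model$atoms))
  structure(list(centers = model$xyz, amplitudes = amp, width = width),
            class = "gaussian_mixture")
}

#' Gaussian width used to emulate a stated resolution
#' @param resolution resolution in Angstrom
#' @return Gaussian sigma in Angstrom
#' @export
sigma_from_resolution <- function(resolution) 0.225 * resolution

#' Compute the hydrogen overlay of a model
#'
#' Hydrogens are a pure function of the heavy-atom coordinates: each is
#' placed from template internal coordinates with rotatable torsions fixed
#' (zero-torsion convention). The input model is unchanged.
#'
#' @param model an `atomic_model`
#' @param templates result of [load_templates()]
#' @param topo optional precompiled topology (saves recompiling)
#' @return list with `xyz` (nH x 3), `name`, `parent` (heavy-atom index)
#' @export
add_hydrogens <- function(model, templates = load_templates(), topo = NULL) {
  if (is.null(topo)) topo <- compile_topology(model, templates)
  hxyz <- place_hydrogens(model$xyz, topo)
  list(xyz = hxyz,
       name = if (is.null(topo$hydrogens)) character(0) else topo$hydrogens$h,
       parent = if (is.null(topo$hydrogens)) integer(0) else topo$hydrogens$ib)
}

#' Write a model (or a model series) to PDB
#'
#' A single model is written as a plain PDB; a list of models sharing one
#' atom ordering is written as a multi-model PDB (MODEL/ENDMDL records) in
#' trajectory order.
#'
#' @param model an `atomic_model`, or a list of them for a series
#' @param path output file
#' @param format `"pdb"` or `"cif"`
#' @return `path`, invisibly
#' @export
write_model <- function(model, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  if (inherits(model, "atomic_model")) models <- list(model)
  else {
    models <- model
    n <- vapply(models, function(m) nrow(m$atoms), 0L)
    if (length(unique(n)) != 1)
      stop("inconsistent atom counts across the model series")
  }
  if (format == "cif") {
    if (length(models) > 1) stop("series output supports PDB only")
    return(write_mmcif(models[[1]], path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (k in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(format_pdb_records(models[[k]]), con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  invisible(path)
}

#' @rdname write_model
#' @param models list of `atomic_model` sharing one atom ordering
#' @export
write_series <- function(models, path) write_model(models, path, "pdb")

format_pdb_records <- function(model) {
  a <- model$atoms
  nm <- a$atom
  # PDB atom-name column convention: 1-char elements start in column 14
  pad <- ifelse(nchar(nm) < 4 & nchar(a$element) == 1,
                paste0(" ", formatC(nm, width = -3)), formatC(nm, width = -4))
  sprintf("ATOM  %5d %s%s%s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(a)), substr(pad, 1, 4), " ",
          formatC(a$res_name, width = -3), a$chain, a$res_seq,
          ifelse(a$ins == "", " ", a$ins),
          model$xyz[, 1], model$xyz[, 2], model$xyz[, 3],
          a$occ, 0, a$element)
}

write_mmcif <- function(model, path) {
  a <- model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_model", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
               "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy"), con)
  writeLines(sprintf("ATOM %d %s %s %s %s %d %s %.3f %.3f %.3f %.2f",
                     seq_len(nrow(a)), a$element, a$atom, a$res_name,
                     a$chain, a$res_seq, ifelse(a$ins == "", "?", a$ins),
                     model$xyz[, 1], model$xyz[, 2], model$xyz[, 3], a$occ),
             con)
  writeLines("#", con)
  invisible(path)
}

#' Replace the coordinates of a model
#' @param model an `atomic_model`
#' @param xyz new N x 3 coordinates
#' @return the model with updated coordinates (metadata untouched)
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms))
  model$xyz <- unname(as.matrix(xyz))
  model
}
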