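# Structure / pose / manifest I/O.
#
# PDB and PDBQT are parsed by fixed columns (x,y,z in columns 31-54), never by
# whitespace splitting: docking engines emit irregular spacing in PDBQT.

.AD_TYPE_ELEMENT <- c(
  A = "C", C = "C", N = "N", NA. = "N", OA = "O", O = "O", S = "S", SA = "S",
  H = "H", HD = "H", HS = "H", P = "P", F = "F", Cl = "Cl", CL = "Cl",
  Br = "Br", BR = "Br", I = "I", Zn = "Zn", ZN = "Zn", Mg = "Mg", MG = "Mg",
  Mn = "Mn", Fe = "Fe", Ca = "Ca"
)

.substr_trim <- function(line, a, b) trimws(substring(line, a, b))

.num_field <- function(line, a, b, what, lineno) {
  s <- .substr_trim(line, a, b)
  v <- suppressWarnings(as.numeric(s))
  if (!length(s) || !nzchar(s) || is.na(v))
    stop(sprintf("malformed %s field '%s' on line %d", what, s, lineno), call. = FALSE)
  v
}

.element_from_name <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substring(s, 1, 2))
  if (two %in% c("CL", "BR", "ZN", "MG", "FE", "MN", "CA", "NA", "SE"))
    return(paste0(substring(two, 1, 1), tolower(substring(two, 2, 2))))
  toupper(substring(s, 1, 1))
}

.parse_atom_line <- function(line, lineno, dialect) {
  if (substring(line, 27, 27) != " " && nzchar(trimws(substring(line, 27, 27))))
    stop(sprintf("insertion code '%s' on line %d: insertion codes are unsupported",
                 substring(line, 27, 27), lineno), call. = FALSE)
  rec <- list(
    serial = as.integer(.num_field(line, 7, 11, "serial", lineno)),
    name = .substr_trim(line, 13, 16),
    resname = .substr_trim(line, 18, 20),
    chain = substring(line, 22, 22),
    resseq = as.integer(.num_field(line, 23, 26, "residue number", lineno)),
    x = .num_field(line, 31, 38, "x coordinate", lineno),
    y = .num_field(line, 39, 46, "y coordinate", lineno),
    z = .num_field(line, 47, 54, "z coordinate", lineno)
  )
  if (dialect == "pdbqt") {
    chg <- suppressWarnings(as.numeric(.substr_trim(line, 67, 76)))
    typ <- .substr_trim(line, 78, 80)
    rec$charge <- if (length(chg) && !is.na(chg)) chg else NA_real_
    rec$atom_type <- if (nzchar(typ)) typ else NA_character_
    el <- .AD_TYPE_ELEMENT[typ]
    rec$element <- if (!is.na(el)) unname(el) else .element_from_name(rec$name)
  } else {
    el <- .substr_trim(line, 77, 78)
    rec$element <- if (nzchar(el)) {
      paste0(toupper(substring(el, 1, 1)), tolower(substring(el, 2)))
    } else .element_from_name(rec$name)
  }
  rec
}

.atoms_df <- function(records) {
  df <- do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df[, c("serial", "name", "element", "resname", "resseq", "chain", "x", "y", "z",
         intersect(c("charge", "atom_type"), names(df)))]
}

#' Read a receptor structure from PDB or PDBQT
#'
#' One [Structure-class] atom per `ATOM`/`HETATM` record. Coordinates are
#' taken from the fixed PDB columns 31-54; in the `pdbqt` dialect the partial
#' charge and AutoDock atom type columns are retained as `charge` and
#' `atom_type` atom metadata and the element is inferred from the atom type.
#'
#' @param path path to the file.
#' @param dialect `"pdb"` or `"pdbqt"`.
#' @param label snapshot label stored on the result; defaults to the file name.
#' @return a [Structure-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000           C"), pdb)
#' nAtoms(readStructure(pdb))
#' @export
readStructure <- function(path, dialect = c("pdb", "pdbqt"), label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  recs <- mapply(.parse_atom_line, lines[sel], which(sel),
                 MoreArgs = list(dialect = dialect), SIMPLIFY = FALSE)
  new("Structure", atoms = .atoms_df(recs), label = label)
}

.format_atom_name <- function(name) {
  # element-left-justified-at-column-14 convention for short names
  if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
}

.pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z, element) {
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, .format_atom_name(name), resname, chain, resseq, x, y, z, element)
}

#' Write a Structure as a PDB file
#'
#' Fixed-column output; coordinates printed to 3 decimals (the format's
#' precision). Intended for fixtures and for feeding external tools.
#'
#' @param x a [Structure-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
  a <- atoms(x)
  lines <- mapply(.pdb_atom_line, a$serial, a$name, a$resname, a$chain, a$resseq,
                  a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

.DEFAULT_ENERGY_PATTERNS <- c(
  "VINA RESULT:\\s*(-?[0-9]*\\.?[0-9]+)",
  "[Bb]inding [Ee]nergy\\s*[=:]?\\s*(-?[0-9]*\\.?[0-9]+)",
  "Estimated Free Energy of Binding\\s*[=:]\\s*(-?[0-9]*\\.?[0-9]+)"
)

.scan_model_energy <- function(remarks, patterns) {
  for (p in patterns) {
    hit <- regmatches(remarks, regexec(p, remarks))
    for (h in hit) if (length(h) == 2L) return(as.numeric(h[2L]))
  }
  NA_real_
}

#' Read a ligand pose bundle
#'
#' Accepts either the toolkit's native JSON pose table (the normative fixture
#' format) or a multi-model PDBQT file (`MODEL`/`ENDMDL` blocks, one docking
#' energy per model on a `REMARK` line). All models must share the atom
#' count; each pose's energy (kcal/mol) is attached in file order.
#'
#' @param path path to a `.json` pose table or multi-model PDBQT file.
#' @param format `"auto"` (by extension), `"json"` or `"pdbqt"`.
#' @param energyPatterns regexes with one capture group tried in order
#'   against each model's REMARK lines to extract the docking energy.
#' @param permissive if `TRUE`, a model without an energy annotation gets
#'   `NaN` instead of raising an error.
#' @return a [PoseBundle-class].
#' @export
readPoseBundle <- function(path, format = c("auto", "json", "pdbqt"),
                           energyPatterns = .DEFAULT_ENERGY_PATTERNS,
                           permissive = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "pdbqt"
  if (format == "json") return(.read_pose_json(path))
  .read_pose_pdbqt(path, energyPatterns, permissive)
}

.read_pose_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$ligand_id) || is.null(j$poses)) stop("not a pose table: ", path, call. = FALSE)
  poses <- j$poses
  cl <- if (is.data.frame(poses)) {
    lapply(seq_len(nrow(poses)), function(i) {
      m <- poses$coords[[i]]
      matrix(as.numeric(m), ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
    })
  } else {
    lapply(poses, function(p) matrix(as.numeric(p$coords), ncol = 3L,
                                     dimnames = list(NULL, c("x", "y", "z"))))
  }
  en <- if (is.data.frame(poses)) as.numeric(poses$energy)
        else vapply(poses, function(p) as.numeric(p$energy), 0)
  meta <- as.data.frame(j$atoms, stringsAsFactors = FALSE)
  new("PoseBundle", ligandId = j$ligand_id, coords = cl, energies = en, atomMeta = meta)
}

.read_pose_pdbqt <- function(path, energyPatterns, permissive) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L) { starts <- 1L; ends <- length(lines) }
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL in ", path, call. = FALSE)
  coords <- list(); en <- numeric(0); meta <- NULL
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    off <- starts[k] - 1L
    sel <- grepl("^(ATOM  |HETATM)", block)
    if (!any(sel)) stop(sprintf("model %d has no atoms", k), call. = FALSE)
    recs <- mapply(.parse_atom_line, block[sel], off + which(sel),
                   MoreArgs = list(dialect = "pdbqt"), SIMPLIFY = FALSE)
    a <- .atoms_df(recs)
    if (is.null(meta)) {
      meta <- a[, c("name", "element")]
    } else if (nrow(a) != nrow(meta)) {
      stop(sprintf("model %d has %d atoms; model 1 has %d", k, nrow(a), nrow(meta)),
           call. = FALSE)
    }
    e <- .scan_model_energy(block[grepl("^REMARK", block)], energyPatterns)
    if (is.na(e)) {
      if (!permissive)
        stop(sprintf("model %d carries no recognizable energy REMARK", k), call. = FALSE)
      e <- NaN
    }
    coords[[k]] <- as.matrix(a[, c("x", "y", "z")])
    en[k] <- e
  }
  rownames(meta) <- NULL
  new("PoseBundle",
      ligandId = sub("\\.(pdbqt|pdb)$", "", basename(path), ignore.case = TRUE),
      coords = coords, energies = en, atomMeta = meta)
}

#' Write a pose bundle
#'
#' `"json"` writes the native pose table (full double precision); `"pdbqt"`
#' writes a multi-model file with a `REMARK VINA RESULT`-style energy line
#' per model and coordinates at the format's 3-decimal precision.
#'
#' @param x a [PoseBundle-class].
#' @param path output path.
#' @param format `"json"` or `"pdbqt"`.
#' @return `path`, invisibly.
#' @export
writePoseBundle <- function(x, path, format = c("json", "pdbqt")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      ligand_id = ligandId(x),
      atoms = atomMeta(x),
      poses = lapply(seq_len(nPoses(x)), function(i)
        list(energy = energies(x)[i], coords = unname(poseCoords(x, i))))
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  meta <- atomMeta(x)
  out <- character(0)
  for (i in seq_len(nPoses(x))) {
    cm <- poseCoords(x, i)
    out <- c(out, sprintf("MODEL %8d", i),
             sprintf("REMARK VINA RESULT:    %8.3f      0.000      0.000", energies(x)[i]),
             mapply(.pdb_atom_line, seq_len(nrow(cm)), meta$name, "LIG", "Z", 1L,
                    cm[, 1], cm[, 2], cm[, 3], meta$element),
             "ENDMDL")
  }
  writeLines(out, path)
  invisible(path)
}

#' Build a library manifest in memory
#'
#' @param entries data.frame with `ligand_id`, `label` (`TP`/`decoy`) and
#'   optional `ec50_nM`.
#' @param ec50Threshold EC50 ceiling (nM) a TP may carry; default 1.0.
#' @return a [LibraryManifest-class].
#' @export
makeManifest <- function(entries, ec50Threshold = 1.0) {
  entries$ligand_id <- as.character(entries$ligand_id)
  entries$label <- as.character(entries$label)
  blank <- is.na(entries$label) | !nzchar(trimws(entries$label))
  if (any(blank))
    stop("empty label on row(s): ", paste(which(blank), collapse = ", "), call. = FALSE)
  new("LibraryManifest", entries = entries, ec50Threshold = ec50Threshold)
}

#' Read a TP/decoy library manifest from CSV
#'
#' Expects columns `ligand_id`, `label` and optionally `ec50_nM`. Duplicated
#' ligand ids, unknown labels and blank labels are errors that name the
#' offending row.
#'
#' @inheritParams makeManifest
#' @param path CSV path.
#' @return a [LibraryManifest-class].
#' @export
readManifest <- function(path, ec50Threshold = 1.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand_id", "label") %in% names(df)))
    stop("manifest needs ligand_id and label columns", call. = FALSE)
  makeManifest(df, ec50Threshold = ec50Threshold)
}

#' Write a manifest to CSV
#' @param x a [LibraryManifest-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(x, path) {
  utils::write.csv(manifestEntries(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
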