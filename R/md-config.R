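# Molecular configurations: labeled coordinates in an orthorhombic box.
# Internal units: nm.

# Default residue-name -> molecule-type mapping for GRO files.
.default_type_map <- c(
  SOL = "water", WAT = "water", HOH = "water", TIP3 = "water",
  ACT = "acetone", ACE = "acetone", THF = "thf", DXN = "dxn",
  DMS = "dmso", DMSO = "dmso", LIG = "lignin", L1 = "lignin",
  L2 = "lignin", L3 = "lignin"
)

#' Construct a molecular configuration
#'
#' @param coordinates N x 3 numeric matrix, nm.
#' @param element Per-atom element symbol.
#' @param atom_name Per-atom label (e.g. `"OW"`, `"HW1"`).
#' @param molecule_id Per-atom integer molecule index; atoms of one
#'   molecule must be contiguous.
#' @param molecule_type Per-atom molecule-type label (e.g. `"water"`).
#' @param box Orthorhombic box edge lengths, length-3 numeric, nm.
#' @return Object of class `molecular_configuration`.
#' @export
molecular_configuration <- function(coordinates, element, atom_name,
                                    molecule_id, molecule_type, box) {
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  stopifnot(ncol(coordinates) == 3, length(element) == n,
            length(atom_name) == n, length(molecule_id) == n,
            length(molecule_type) == n, length(box) == 3)
  if (any(!is.finite(coordinates))) stop("coordinates must be finite")
  if (any(box <= 0)) stop("box edges must be positive")
  r <- rle(as.integer(molecule_id))
  if (anyDuplicated(r$values)) {
    stop("molecule_id must be contiguous within molecules")
  }
  structure(list(coordinates = unname(coordinates),
                 element = as.character(element),
                 atom_name = as.character(atom_name),
                 molecule_id = as.integer(molecule_id),
                 molecule_type = as.character(molecule_type),
                 box = as.numeric(box)),
            class = "molecular_configuration")
}

#' @export
print.molecular_configuration <- function(x, ...) {
  types <- table(x$molecule_type[!duplicated(x$molecule_id)])
  cat(sprintf("molecular_configuration: %d atoms, %d molecules, box %s nm\n",
              nrow(x$coordinates), length(unique(x$molecule_id)),
              paste(signif(x$box, 4), collapse = " x ")))
  cat("  molecules:", paste(names(types), types, sep = ":", collapse = ", "),
      "\n")
  invisible(x)
}

# Element symbol from an atom name: leading letters, first matched against
# two-letter then one-letter symbols.
.element_from_name <- function(atom_name) {
  lead <- toupper(sub("^([A-Za-z]+).*$", "\\1", atom_name))
  vapply(lead, function(s) {
    two <- paste0(substr(s, 1, 1), tolower(substr(s, 2, 2)))
    if (nchar(s) >= 2 && two %in% .element_table$symbol) return(two)
    one <- substr(s, 1, 1)
    if (one %in% .element_table$symbol) return(one)
    one
  }, character(1), USE.NAMES = FALSE)
}

.parse_gro_frame <- function(lines, offset, type_map) {
  # frame layout: title, atom count, atoms, box line
  natoms <- suppressWarnings(as.integer(trimws(lines[offset + 2])))
  if (is.na(natoms)) stop("GRO: bad atom count at line ", offset + 2)
  need <- offset + 3 + natoms
  if (length(lines) < need) stop("GRO: truncated frame at line ", offset + 2)
  at <- lines[(offset + 3):(offset + 2 + natoms)]
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  aname <- trimws(substr(at, 11, 15))
  xyz <- matrix(suppressWarnings(as.numeric(
    c(substr(at, 21, 28), substr(at, 29, 36), substr(at, 37, 44)))),
    ncol = 3)
  if (anyNA(xyz) || anyNA(resid)) {
    stop("GRO: malformed atom line near line ", offset + 3)
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[need]),
                                              "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3])) {
    stop("GRO: malformed box line at line ", need)
  }
  mtype <- unname(type_map[resname])
  mtype[is.na(mtype)] <- tolower(resname[is.na(mtype)])
  cfg <- molecular_configuration(xyz, .element_from_name(aname), aname,
                                 resid, mtype, box[1:3])
  list(config = cfg, next_offset = need)
}

#' Read molecular configurations from a GRO file
#'
#' Parses the fixed-column GROMACS coordinate format (nm; final line is the
#' box).  Multi-frame concatenations are supported.  Molecule type is
#' resolved from the residue name through `type_map` (defaults cover
#' water/acetone/THF/DXN/DMSO/lignin residue names; unmapped residue names
#' become their lower-cased residue name).
#'
#' @param path Path to a `.gro` file.
#' @param type_map Named character vector, residue name -> molecule type.
#' @return A single `molecular_configuration`, or a list of them for a
#'   multi-frame file.
#' @export
read_gro <- function(path, type_map = NULL) {
  tm <- .default_type_map
  if (!is.null(type_map)) tm[names(type_map)] <- type_map
  lines <- readLines(path)
  frames <- list()
  off <- 0
  while (off < length(lines)) {
    if (!nzchar(trimws(paste(lines[(off + 1):min(off + 2, length(lines))],
                             collapse = "")))) break
    fr <- .parse_gro_frame(lines, off, tm)
    frames[[length(frames) + 1]] <- fr$config
    off <- fr$next_offset
  }
  if (length(frames) == 0) stop("no frames in ", path)
  if (length(frames) == 1) frames[[1]] else frames
}

#' Write a molecular configuration as GRO
#'
#' @param config A `molecular_configuration` or list of them (multi-frame).
#' @param path Output path.
#' @param title Title line.
#' @export
write_gro <- function(config, path, title = "lnptools configuration") {
  if (inherits(config, "molecular_configuration")) config <- list(config)
  con <- file(path, "w")
  on.exit(close(con))
  rev_map <- stats::setNames(names(.default_type_map),
                             .default_type_map)[!duplicated(.default_type_map)]
  for (cfg in config) {
    resname <- rev_map[cfg$molecule_type]
    resname[is.na(resname)] <- toupper(substr(
      cfg$molecule_type[is.na(resname)], 1, 5))
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     cfg$molecule_id %% 100000, resname,
                     substr(cfg$atom_name, 1, 5),
                     seq_along(cfg$atom_name) %% 100000,
                     cfg$coordinates[, 1], cfg$coordinates[, 2],
                     cfg$coordinates[, 3])
    writeLines(c(title, sprintf("%d", nrow(cfg$coordinates)), lines,
                 sprintf("%10.5f%10.5f%10.5f", cfg$box[1], cfg$box[2],
                         cfg$box[3])), con)
  }
  invisible(path)
}

#' Read an extended XYZ configuration
#'
#' XYZ coordinates are in Angstrom and converted to nm.  The box is read
#' from the comment line, either as `Lattice="ax 0 0 0 by 0 0 0 cz"`
#' (orthorhombic; off-diagonal terms must be zero) or as the first three
#' numbers found.  Since plain XYZ carries no molecule information, a
#' sidecar CSV with per-atom columns `molecule_id,molecule_type` is
#' required whenever the system has more than one molecule; single-molecule
#' files default to one molecule of type `"molecule"`.
#'
#' @param path Path to an `.xyz` file.
#' @param typing_sidecar Optional path to the per-atom typing CSV.
#' @return A `molecular_configuration`.
#' @export
read_xyz <- function(path, typing_sidecar = NULL) {
  lines <- readLines(path)
  natoms <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(natoms) || length(lines) < natoms + 2) {
    stop("malformed XYZ file: ", path)
  }
  comment <- lines[2]
  lat <- regmatches(comment,
                    regexpr('Lattice="[^"]*"', comment))
  if (length(lat) == 1) {
    v <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
    if (length(v) != 9 || any(v[c(2, 3, 4, 6, 7, 8)] != 0)) {
      stop("XYZ Lattice is not orthorhombic")
    }
    box_A <- v[c(1, 5, 9)]
  } else {
    nums <- as.numeric(regmatches(comment,
                                  gregexpr("-?[0-9]+\\.?[0-9]*", comment))[[1]])
    if (length(nums) < 3) stop("no box on XYZ comment line")
    box_A <- nums[1:3]
  }
  rows <- strsplit(trimws(lines[3:(natoms + 2)]), "\\s+")
  el <- vapply(rows, `[[`, character(1), 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric XYZ coordinates")
  if (!is.null(typing_sidecar)) {
    side <- utils::read.csv(typing_sidecar, stringsAsFactors = FALSE)
    if (nrow(side) != natoms ||
        !all(c("molecule_id", "molecule_type") %in% names(side))) {
      stop("typing sidecar must have one molecule_id,molecule_type row ",
           "per atom")
    }
    mid <- side$molecule_id; mtype <- side$molecule_type
  } else {
    if (length(unique(el)) > 1 && natoms > 4) {
      stop("multi-type XYZ system requires a typing sidecar")
    }
    mid <- rep(1L, natoms); mtype <- rep("molecule", natoms)
  }
  molecular_configuration(xyz / 10, el, el, mid, mtype, box_A / 10)
}

#' Read a configuration file of either supported format
#'
#' @param path File path; format from extension unless given.
#' @param format `"gro"` or `"xyz"`.
#' @param typing_sidecar Optional typing CSV for XYZ input.
#' @return A `molecular_configuration` (or list for multi-frame GRO).
#' @export
read_configuration <- function(path, format = c("auto", "gro", "xyz"),
                               typing_sidecar = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("gro", "xyz")) stop("unrecognized format: ", format)
  }
  if (format == "gro") read_gro(path) else read_xyz(path, typing_sidecar)
}
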