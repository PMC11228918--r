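#' Per-atom topology table for trajectory analysis
#'
#' Wraps a data.frame with one row per atom, ordered by 0-based `atom_id`:
#' `atom_id, element, mass, charge, lj_epsilon, lj_sigma, molecule_id,
#' molecule_type, is_donor, is_acceptor, is_donor_h, donor_of, ring_pos`.
#' `molecule_type` is "solute" or "solvent"; `donor_of` is the 0-based atom
#' id of the donor heavy atom a donor hydrogen is bonded to (NA otherwise);
#' `ring_pos` is 1-6 for the six ring atoms of a molecule, 0 for non-ring
#' atoms.
#'
#' @param atoms The per-atom data.frame described above. Missing role/ring
#'   columns default to "off".
#' @return An object of class `topology`.
#' @export
topology <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("atom_id", "element", "mass", "charge", "lj_epsilon", "lj_sigma",
            "molecule_id", "molecule_type")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("topology is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("is_donor", "is_acceptor", "is_donor_h"))
    if (is.null(atoms[[col]])) atoms[[col]] <- FALSE else
      atoms[[col]] <- as.logical(atoms[[col]])
  if (is.null(atoms$donor_of)) atoms$donor_of <- NA_integer_
  if (is.null(atoms$ring_pos)) atoms$ring_pos <- 0L
  atoms <- atoms[order(atoms$atom_id), ]
  if (!identical(as.integer(atoms$atom_id), seq_len(nrow(atoms)) - 1L))
    stop("atom_id must be 0-based and contiguous", call. = FALSE)
  mids <- sort(unique(atoms$molecule_id))
  if (!identical(as.integer(mids), seq_along(mids)))
    stop("molecule_id must be 1-based and contiguous", call. = FALSE)
  if (!all(atoms$molecule_type %in% c("solute", "solvent")))
    stop("molecule_type must be 'solute' or 'solvent'", call. = FALSE)
  ring_n <- tapply(atoms$ring_pos > 0, atoms$molecule_id, sum)
  if (any(!ring_n %in% c(0, 6)))
    stop("ring atom lists must have exactly 6 atoms per molecule",
         call. = FALSE)
  dh <- which(atoms$is_donor_h)
  if (length(dh)) {
    don <- atoms$donor_of[dh]
    if (any(is.na(don)))
      stop("every donor hydrogen needs a donor_of atom id", call. = FALSE)
    if (any(!atoms$is_donor[don + 1L]))
      stop("donor_of must reference an atom flagged as donor", call. = FALSE)
    if (any(atoms$molecule_id[don + 1L] != atoms$molecule_id[dh]))
      stop("a donor hydrogen must belong to its donor's molecule",
           call. = FALSE)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 n_atoms = nrow(atoms),
                 n_molecules = length(mids)),
            class = "topology")
}

#' Read a topology CSV
#'
#' @param path CSV file with the columns documented in [topology()].
#' @return A `topology`.
#' @export
read_topology <- function(path) {
  topology(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a topology CSV
#'
#' @param topo A [topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  stopifnot(inherits(topo, "topology"))
  utils::write.csv(topo$atoms, path, row.names = FALSE)
  invisible(path)
}

new_frame <- function(time, box, coords) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive orthorhombic edge lengths (nm); ",
         "triclinic boxes are not supported", call. = FALSE)
  coords <- as.matrix(coords)
  list(time = time, box = box, coords = coords)
}

#' Read an extended-XYZ trajectory
#'
#' The format is standard XYZ with the comment line carrying the periodic
#' box and the frame time: `box <Lx> <Ly> <Lz> time <ps>` (lengths in nm).
#' Only orthorhombic boxes are supported.
#'
#' @param path File path.
#' @param topo Optional [topology()]; if given, every frame's atom count must
#'   match it.
#' @return An object of class `md_trajectory`: a list of frames, each with
#'   `time` (ps), `box` (nm, length 3) and `coords` (n x 3 matrix, nm).
#' @export
read_xyz_trajectory <- function(path, topo = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  frames <- list()
  i <- 1L; fr <- 0L
  while (i <= length(lines)) {
    fr <- fr + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0)
      stop("frame ", fr, ": malformed atom-count line", call. = FALSE)
    if (i + 1L + nat > length(lines))
      stop("frame ", fr, ": truncated (expected ", nat, " atom lines)",
           call. = FALSE)
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(tok) < 6 || tok[1] != "box" || tok[5] != "time")
      stop("frame ", fr,
           ": comment line must be 'box Lx Ly Lz time <ps>'", call. = FALSE)
    box <- suppressWarnings(as.numeric(tok[2:4]))
    tm <- suppressWarnings(as.numeric(tok[6]))
    if (any(is.na(box)) || is.na(tm))
      stop("frame ", fr, ": malformed box line", call. = FALSE)
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(atom_lines), "\\s+")
    if (any(lengths(parts) < 4))
      stop("frame ", fr, ": malformed atom line", call. = FALSE)
    m <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(parts, `[`, 2:4)))), ncol = 3, byrow = TRUE)
    if (any(is.na(m)))
      stop("frame ", fr, ": non-numeric coordinates", call. = FALSE)
    if (!is.null(topo) && nat != topo$n_atoms)
      stop("frame ", fr, ": atom count ", nat,
           " does not match topology (", topo$n_atoms, ")", call. = FALSE)
    frames[[fr]] <- new_frame(tm, box, m)
    i <- i + 2L + nat
  }
  structure(frames, class = "md_trajectory")
}

#' Write an extended-XYZ trajectory
#'
#' @param trajectory An `md_trajectory` (list of frames).
#' @param topo A [topology()] supplying element symbols.
#' @param path Output path.
#' @param digits Coordinate precision, decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(trajectory, topo, path, digits = 6) {
  stopifnot(inherits(topo, "topology"))
  con <- file(path, "w"); on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in trajectory) {
    writeLines(as.character(nrow(f$coords)), con)
    writeLines(sprintf("box %.6f %.6f %.6f time %.6f",
                       f$box[1], f$box[2], f$box[3], f$time), con)
    writeLines(sprintf(fmt, topo$atoms$element,
                       f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
  }
  invisible(path)
}
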