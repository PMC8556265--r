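#' @importFrom rlang .data %||% abort warn
#' @importFrom dplyr filter mutate arrange group_by ungroup summarise select
#'   distinct n row_number bind_rows left_join count across first
#' @importFrom tibble tibble as_tibble
NULL

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")

#' Construct a structure atom table
#'
#' The central container of the package is a tidy atom table: one row per
#' atom, carrying author chain/residue numbering, coordinates in Angstrom,
#' isotropic B-factors and occupancies.  [as_structure()] validates a plain
#' data frame and stamps it with the `aqp_structure` class plus entry-level
#' metadata (identifier, space group, unit cell).
#'
#' Required columns: `chain`, `resno`, `resname`, `atom`, `element`,
#' `x`, `y`, `z`.  Optional columns are filled with defaults: `insert` (""),
#' `alt` (""), `occ` (1), `b` (0), `eleno` (row number), `hetero`, `water`,
#' `primary` (highest-occupancy alternate conformer flag).
#'
#' @param atoms data frame of atoms.
#' @param id entry identifier.
#' @param space_group space-group symbol, or `NA`.
#' @param cell numeric length-6 unit cell (a, b, c in Angstrom; alpha, beta,
#'   gamma in degrees), or `NULL`.
#' @return an `aqp_structure` tibble.
#' @export
as_structure <- function(atoms, id = "model", space_group = NA_character_,
                         cell = NULL) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(atoms) > 0 && !all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("atom coordinates must be finite")
  }
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"alt" %in% names(atoms)) atoms$alt <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"eleno" %in% names(atoms)) atoms$eleno <- seq_len(nrow(atoms))
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  if (nrow(atoms) > 0 && (any(atoms$occ < 0 | atoms$occ > 1))) {
    abort("occupancies must lie in [0, 1]")
  }
  if (nrow(atoms) > 0 && any(atoms$b < 0)) abort("B-factors must be >= 0")
  atoms$element <- toupper(trimws(atoms$element))
  if (!"water" %in% names(atoms)) {
    atoms$water <- toupper(atoms$resname) %in% WATER_RESNAMES
  }
  if (!"hetero" %in% names(atoms)) atoms$hetero <- atoms$water
  atoms <- flag_primary_conformers(atoms)
  structure(atoms,
            class = c("aqp_structure", class(as_tibble(atoms))),
            id = id, space_group = space_group, cell = cell)
}

# Primary alternate-location conformer: highest occupancy, ties broken by
# file order.  All downstream analyses use primary conformers only.
flag_primary_conformers <- function(atoms) {
  if (nrow(atoms) == 0) {
    atoms$primary <- logical(0)
    return(atoms)
  }
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname,
               atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  primary <- logical(nrow(atoms))
  primary[ord[!duplicated(key[ord])]] <- TRUE
  atoms$primary <- primary
  atoms
}

#' @export
print.aqp_structure <- function(x, ...) {
  cat(sprintf("<aqp_structure '%s'> %d atoms, %d chains, %d waters\n",
              attr(x, "id") %||% "?", nrow(x),
              length(unique(x$chain[!x$hetero])),
              length(unique(paste(x$chain, x$resno, x$insert)[x$water]))))
  if (!is.null(attr(x, "cell"))) {
    cat("cell:", paste(signif(attr(x, "cell"), 6), collapse = " "),
        " space group:", attr(x, "space_group"), "\n")
  }
  NextMethod()
}

guess_element <- function(name, resname) {
  name <- trimws(name)
  two <- toupper(substr(name, 1, 2))
  known2 <- c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA", "SE", "SI", "CU")
  ifelse(two %in% known2 & !(toupper(resname) %in% c("HOH", "WAT")),
         two, toupper(substr(gsub("[^A-Za-z].*", "", name), 1, 1)))
}

#' Read a crystal structure into a tidy atom table
#'
#' Parses PDB or mmCIF coordinate files (via bio3d) into an
#' [as_structure()] atom tibble.  Author chain identifiers and residue
#' numbers are canonical; alternate locations are retained with the
#' highest-occupancy conformer flagged `primary`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param id entry identifier; defaults to the file base name.
#' @return an `aqp_structure` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such structure file: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "mmcif", mmcif = "mmcif",
                     pdb = "pdb", ent = "pdb",
                     abort(paste0("cannot guess structure format from '.",
                                  ext, "'; pass format explicitly")))
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) abort(paste0("failed to parse ", format, " file ",
                                     path, ": ", conditionMessage(e))))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    warn(paste0("no ATOM/HETATM records in ", path))
    at <- data.frame(chain = character(), resno = integer(),
                     resname = character(), atom = character(),
                     element = character(), x = double(), y = double(),
                     z = double())
    return(as_structure(at, id = id %||% basename(path)))
  }
  element <- toupper(trimws(at$elesy %||% ""))
  bad <- is.na(element) | element == ""
  if (any(bad)) element[bad] <- guess_element(at$elety[bad], at$resid[bad])
  atoms <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname = toupper(as.character(at$resid)),
    atom = as.character(at$elety),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    element = element,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    eleno = as.integer(at$eleno),
    hetero = at$type == "HETATM")
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$water <- atoms$resname %in% WATER_RESNAMES
  atoms$hetero <- atoms$hetero | atoms$water
  cell <- NULL
  sg <- NA_character_
  if (!is.null(pdb$cryst1)) {
    cell <- as.numeric(pdb$cryst1$cell)
    sg <- pdb$cryst1$sgroup %||% NA_character_
  }
  as_structure(atoms, id = id %||% toupper(sub("\\..*$", "", basename(path))),
               space_group = sg, cell = cell)
}

#' Write an atom table as a PDB file
#'
#' @param model `aqp_structure` (or compatible data frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  model <- as_structure(model, id = attr(model, "id") %||% "model")
  het <- model$hetero
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
    type = ifelse(het, "HETATM", "ATOM"),
    resno = model$resno, resid = model$resname,
    eleno = model$eleno, elety = model$atom,
    chain = ifelse(model$chain == "", " ", model$chain),
    insert = model$insert, alt = ifelse(model$alt == "", "", model$alt),
    o = model$occ, b = model$b, elesy = model$element)
  invisible(path)
}

is_hydrogen <- function(element) element %in% c("H", "D")

#' Entity census of a structure
#'
#' Counts non-hydrogen atoms by entity class, water molecules and protein
#' residues, the way deposition tables report them.  Alternate locations of
#' one atom are counted once (primary conformers only); hydrogens are
#' excluded throughout.
#'
#' @param model `aqp_structure`.
#' @return one-row tibble: `non_h_atoms`, `macromolecule_atoms`,
#'   `ligand_atoms`, `water_atoms`, `water_molecules`, `protein_residues`.
#' @export
count_entities <- function(model) {
  a <- model[model$primary & !is_hydrogen(model$element), , drop = FALSE]
  macro <- !a$hetero
  lig <- a$hetero & !a$water
  wat <- a$water
  wat_mol <- length(unique(paste(a$chain, a$resno, a$insert)[wat]))
  prot_res <- length(unique(paste(a$chain, a$resno, a$insert)[macro]))
  tibble(non_h_atoms = nrow(a),
         macromolecule_atoms = sum(macro),
         ligand_atoms = sum(lig),
         water_atoms = sum(wat),
         water_molecules = wat_mol,
         protein_residues = prot_res)
}

#' Mean isotropic B-factor over a selection
#'
#' Unweighted arithmetic mean of per-atom B over non-hydrogen primary
#' conformers of the chosen entity class.
#'
#' @param model `aqp_structure`.
#' @param selection one of `"all"`, `"macromolecule"`, `"ligand"`, `"water"`.
#' @return mean B in Angstrom^2.
#' @export
mean_b_factor <- function(model,
                          selection = c("all", "macromolecule", "ligand",
                                        "water")) {
  selection <- match.arg(selection)
  a <- model[model$primary & !is_hydrogen(model$element), , drop = FALSE]
  keep <- switch(selection,
                 all = rep(TRUE, nrow(a)),
                 macromolecule = !a$hetero,
                 ligand = a$hetero & !a$water,
                 water = a$water)
  if (!any(keep)) abort(paste0("empty selection '", selection, "'"))
  mean(a$b[keep])
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

#' Extract the one-letter sequence of a chain
#'
#' Residues are ordered by author numbering (`resno`, insertion code);
#' nonstandard residues map to `X` (selenomethionine maps to `M` with a
#' modification note).  Numbering gaps are reported in the `gaps` attribute.
#'
#' @param model `aqp_structure`.
#' @param chain_id chain identifier.
#' @return tibble with `resno`, `insert`, `resname`, `aa`; attributes
#'   `sequence` (single string), `gaps` (tibble of numbering gaps) and
#'   `modified` (tibble of nonstandard residues mapped to a standard letter).
#' @export
extract_sequence <- function(model, chain_id) {
  a <- model[model$chain == chain_id & !model$hetero & model$primary, ,
             drop = FALSE]
  if (nrow(a) == 0) {
    abort(paste0("chain '", chain_id, "' not found; available: ",
                 paste(sort(unique(model$chain[!model$hetero])),
                       collapse = ", ")))
  }
  res <- as_tibble(a) |>
    distinct(.data$resno, .data$insert, .data$resname) |>
    arrange(.data$resno, .data$insert)
  res$aa <- unname(AA3TO1[res$resname])
  modified <- res[!is.na(res$aa) & !(res$resname %in% names(AA3TO1)[1:20]), ]
  res$aa[is.na(res$aa)] <- "X"
  gaps <- res |>
    mutate(next_resno = dplyr::lead(.data$resno)) |>
    filter(!is.na(.data$next_resno), .data$next_resno > .data$resno + 1) |>
    select(after = "resno", before = "next_resno")
  structure(select(res, "resno", "insert", "resname", "aa"),
            sequence = paste(res$aa, collapse = ""),
            gaps = gaps, modified = modified,
            class = c("aqp_sequence", class(res)))
}

#' @export
print.aqp_sequence <- function(x, ...) {
  cat(sprintf("<aqp_sequence> %d residues (%d-%d)\n%s\n", nrow(x),
              min(x$resno), max(x$resno), attr(x, "sequence")))
  invisible(x)
}

#' Locate the two pore NPA motifs and their spacing
#'
#' Finds Asn-Pro-Ala tripeptides in a chain sequence and reports the pair
#' flanking the pore together with the number of residues strictly between
#' them (between the Ala of the first motif and the Asn of the second).
#' When more than two motifs occur, the pair whose spacing lies in
#' `spacing_window` and whose midpoint sits closest to the sequence centre
#' is chosen; ambiguity (several admissible pairs tied) is an error.
#'
#' @param sequence an [extract_sequence()] result, or a plain character
#'   string sequence.
#' @param spacing_window admissible inter-motif spacing range (residues).
#' @return one-row tibble: `motif1_start`, `motif2_start` (author numbers
#'   when available, else 1-based indices) and `spacing`.
#' @export
npa_spacing <- function(sequence, spacing_window = c(60, 200)) {
  if (is.character(sequence)) {
    seq_str <- sequence
    resno <- seq_len(nchar(seq_str))
  } else {
    seq_str <- attr(sequence, "sequence")
    resno <- sequence$resno
  }
  hits <- gregexpr("(?=NPA)", seq_str, perl = TRUE)[[1]]
  if (identical(as.integer(hits), -1L)) hits <- integer(0)
  if (length(hits) < 2) {
    abort(sprintf("found %d NPA motif(s); two are required", length(hits)))
  }
  pairs <- expand.grid(i = seq_along(hits), j = seq_along(hits))
  pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
  # spacing counts residues strictly between motif1's Ala and motif2's Asn
  pairs$spacing <- hits[pairs$j] - hits[pairs$i] - 3L
  if (length(hits) > 2) {
    ok <- pairs$spacing >= spacing_window[1] & pairs$spacing <= spacing_window[2]
    if (!any(ok)) {
      abort("no NPA pair with spacing inside the admissible window")
    }
    mid <- (hits[pairs$i] + hits[pairs$j] + 2) / 2
    cen <- abs(mid - (nchar(seq_str) + 1) / 2)
    cen[!ok] <- Inf
    best <- which(cen == min(cen))
    if (length(best) > 1) {
      abort("ambiguous NPA motif pairing: several admissible pairs equally central")
    }
    pairs <- pairs[best, , drop = FALSE]
  } else {
    pairs <- pairs[1, , drop = FALSE]
  }
  tibble(motif1_start = resno[hits[pairs$i]],
         motif2_start = resno[hits[pairs$j]],
         spacing = as.integer(pairs$spacing))
}
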