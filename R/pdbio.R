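#' Read a multi-model PDB file as a conformational ensemble
#'
#' Parses standard `MODEL`/`ENDMDL` blocks (a file without `MODEL` records is
#' treated as a single frame). The atom roster is taken from the first model;
#' atoms of every subsequent model are mapped onto it by
#' `(chain_id, residue_number, atom_name)`, so renumbered serials between
#' models are tolerated. A model whose atom set does not match the roster
#' raises an error naming the first mismatched atom.
#'
#' Alternate locations: records with altloc `"A"` or blank are kept, others
#' dropped. Insertion codes are rejected with an error (author numbering with
#' insertion codes is ambiguous for interval-based domain maps).
#'
#' @param path path to a PDB file
#' @return a [conformational_ensemble()]
#' @seealso [write_multimodel_pdb()]
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model_open <- startsWith(lines, "MODEL")
  is_model_close <- startsWith(lines, "ENDMDL")

  # assign a model index to every line
  model_id <- cumsum(is_model_open)
  if (!any(is_model_open)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L

  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0) stop("no ATOM/HETATM records in ", path)

  parse_atoms <- function(ln_idx) {
    txt <- lines[ln_idx]
    ok <- nchar(txt) >= 54
    if (!all(ok))
      stop("unparseable ATOM line at line ", ln_idx[!ok][1],
           " (shorter than 54 columns)")
    serial <- suppressWarnings(as.integer(substr(txt, 7, 11)))
    atom_name <- trimws(substr(txt, 13, 16))
    altloc <- substr(txt, 17, 17)
    residue_name <- trimws(substr(txt, 18, 20))
    chain_id <- substr(txt, 22, 22)
    residue_number <- suppressWarnings(as.integer(substr(txt, 23, 26)))
    icode <- substr(txt, 27, 27)
    x <- suppressWarnings(as.numeric(substr(txt, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(txt, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(txt, 47, 54)))
    element <- trimws(ifelse(nchar(txt) >= 78, substr(txt, 77, 78), ""))
    bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(residue_number))
    if (length(bad) > 0)
      stop("unparseable ATOM line at line ", ln_idx[bad[1]])
    ins <- which(icode != " " & icode != "")
    if (length(ins) > 0)
      stop("insertion code '", icode[ins[1]], "' at line ", ln_idx[ins[1]],
           " not supported; renumber residues first")
    keep <- altloc %in% c(" ", "", "A")
    data.frame(serial = serial, atom_name = atom_name,
               residue_name = residue_name, residue_number = residue_number,
               chain_id = chain_id, element = element,
               x = x, y = y, z = z,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }

  models <- split(atom_lines, model_id[atom_lines])
  tabs <- lapply(models, parse_atoms)

  roster_tab <- tabs[[1]]
  roster <- roster_tab[, c("serial", "atom_name", "residue_name",
                           "residue_number", "chain_id", "element")]
  rkey <- atom_key(roster)
  if (anyDuplicated(rkey))
    stop("duplicate atom identity in first model: ", rkey[duplicated(rkey)][1])

  na <- nrow(roster)
  nf <- length(tabs)
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  coords[, , 1] <- as.matrix(roster_tab[, c("x", "y", "z")])
  if (nf > 1) {
    for (m in 2:nf) {
      tb <- tabs[[m]]
      mkey <- atom_key(tb)
      pos <- match(rkey, mkey)
      if (anyNA(pos)) {
        miss <- rkey[which(is.na(pos))[1]]
        stop("model ", m, " is missing roster atom ", miss)
      }
      extra <- setdiff(mkey, rkey)
      if (length(extra) > 0)
        stop("model ", m, " contains atom ", extra[1], " absent from model 1")
      coords[, , m] <- as.matrix(tb[pos, c("x", "y", "z")])
    }
  }
  conformational_ensemble(roster, coords)
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' Each frame is emitted as a `MODEL`/`ENDMDL` block with fixed-width
#' coordinates at 3 decimals (the format's native precision; round-tripping is
#' exact to 1e-3 Angstrom).
#'
#' @param ensemble a [conformational_ensemble()]
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ConformationalEnsemble"))
  a <- ensemble$atoms
  nf <- n_frames(ensemble)
  con <- file(path, open = "wt")
  on.exit(close(con))
  # PDB v3 atom-name justification: names shorter than 4 chars start in col 14
  name_field <- ifelse(nchar(a$atom_name) >= 4,
                       substr(a$atom_name, 1, 4),
                       sprintf(" %-3s", a$atom_name))
  for (m in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ensemble$coords[, , m, drop = FALSE]
    recs <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000L, name_field, a$residue_name, a$chain_id,
      a$residue_number, xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1],
      1.0, 0.0, a$element)
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
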