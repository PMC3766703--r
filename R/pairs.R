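#' Define a residue pair for interaction analysis
#'
#' Specifies the two residues of a candidate salt bridge (or other contact),
#' the atom names considered on each side, and the distance criterion.
#'
#' @param residue_a,residue_b list/vector `(chain, number)`, e.g.
#'   `c("A", 710)`
#' @param atoms_a,atoms_b character vectors of atom names considered on each
#'   side (e.g. the charged-group heavy atoms); must be non-empty
#' @param cutoff distance criterion in Angstrom, > 0; the interaction is
#'   "formed" in a frame when the minimum cross-pair distance is <= cutoff
#' @return a `ResiduePairSpec`
#' @export
residue_pair_spec <- function(residue_a, residue_b, atoms_a, atoms_b,
                              cutoff = 4.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (length(atoms_a) == 0 || length(atoms_b) == 0)
    stop("atom selectors must be non-empty")
  norm_res <- function(r) list(chain = as.character(r[[1]]),
                               number = as.integer(r[[2]]))
  structure(list(residue_a = norm_res(residue_a),
                 residue_b = norm_res(residue_b),
                 atoms_a = as.character(atoms_a),
                 atoms_b = as.character(atoms_b),
                 cutoff = as.numeric(cutoff)),
            class = "ResiduePairSpec")
}

#' Default charged-group atom selectors for salt-bridge analysis
#'
#' The side-chain heavy atoms conventionally used for a charged-pair distance
#' criterion. Only residues with a charged side chain are accepted; a
#' Glu-to-Gly substitution, for example, removes the selector entirely and is
#' reported as an error rather than an empty set.
#'
#' @param residue_name 3-letter residue name (ARG, LYS, ASP, GLU or HIS)
#' @return character vector of atom names
#' @export
default_salt_bridge_selectors <- function(residue_name) {
  sel <- switch(toupper(residue_name),
                ARG = c("NH1", "NH2", "NE"),
                LYS = "NZ",
                ASP = c("OD1", "OD2"),
                GLU = c("OE1", "OE2"),
                HIS = c("ND1", "NE2"),
                NULL)
  if (is.null(sel))
    stop("residue ", residue_name,
         " has no charged side-chain selector (expected ARG/LYS/ASP/GLU/HIS)")
  sel
}

#' Read residue-pair definitions from a plain-text config file
#'
#' One pair per line: `chain:resnum:resname chain:resnum:resname [cutoff]`,
#' `#` comments allowed. Atom selectors default to
#' [default_salt_bridge_selectors()] of each residue name; cutoff defaults to
#' 4.0 Angstrom.
#'
#' @param path config file path
#' @return list of [residue_pair_spec()]
#' @export
read_pair_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no pair entries in ", path)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (!length(parts) %in% c(2L, 3L))
      stop("malformed pair entry: ", ln)
    parse_res <- function(tok) {
      f <- strsplit(tok, ":")[[1]]
      if (length(f) != 3) stop("malformed residue token: ", tok)
      list(chain = f[1], number = as.integer(f[2]), name = f[3])
    }
    ra <- parse_res(parts[1]); rb <- parse_res(parts[2])
    cutoff <- if (length(parts) == 3) as.numeric(parts[3]) else 4.0
    residue_pair_spec(c(ra$chain, ra$number), c(rb$chain, rb$number),
                      default_salt_bridge_selectors(ra$name),
                      default_salt_bridge_selectors(rb$name),
                      cutoff = cutoff)
  })
}
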