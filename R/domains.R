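#' Construct a domain map
#'
#' Named inclusive residue intervals in 1-based author numbering, used to
#' summarise correlation maps by domain blocks.
#'
#' @param names character vector of unique domain names
#' @param first integer vector of first residues (inclusive)
#' @param last integer vector of last residues (inclusive)
#' @return a `DomainMap`: data.frame with columns `name`, `first`, `last`
#' @export
domain_map <- function(names, first, last) {
  if (length(names) != length(first) || length(first) != length(last))
    stop("names, first, last must have equal length")
  first <- as.integer(first); last <- as.integer(last)
  bad <- which(first > last)
  if (length(bad) > 0)
    stop("domain '", names[bad[1]], "': first residue ", first[bad[1]],
         " exceeds last residue ", last[bad[1]])
  if (anyDuplicated(names))
    stop("duplicate domain name: ", names[duplicated(names)][1])
  ord <- order(first)
  n <- length(names)
  if (n > 1) {
    f <- first[ord]; l <- last[ord]; nm <- names[ord]
    ov <- which(f[-1] <= l[-n])
    if (length(ov) > 0)
      stop("domains '", nm[ov[1]], "' and '", nm[ov[1] + 1],
           "' have overlapping residue intervals")
  }
  structure(data.frame(name = names, first = first, last = last,
                       stringsAsFactors = FALSE),
            class = c("DomainMap", "data.frame"))
}

#' Read a domain map from a plain-text config file
#'
#' One `name first last` entry per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path config file path
#' @return a [domain_map()]
#' @export
read_domain_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no domain entries in ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad) > 0)
    stop("malformed domain entry (need 'name first last'): ", lines[bad[1]])
  domain_map(vapply(parts, `[`, "", 1),
             as.integer(vapply(parts, `[`, "", 2)),
             as.integer(vapply(parts, `[`, "", 3)))
}

#' The canonical four-domain decomposition of human topoisomerase IB
#'
#' N-terminal (1-214), core (215-635), linker (636-712) and C-terminal
#' (713-765) domains of the 765-residue enzyme — the decomposition used for
#' block summaries of correlation maps.
#'
#' @return a [domain_map()] with four entries
#' @export
htop1_domains <- function() {
  domain_map(c("N-terminal", "core", "linker", "C-terminal"),
             c(1, 215, 636, 713),
             c(214, 635, 712, 765))
}

#' Total residues covered by a domain map
#'
#' @param domains a [domain_map()]
#' @return integer count of residues in the union of the intervals
#' @export
domain_residue_count <- function(domains) {
  stopifnot(inherits(domains, "DomainMap"))
  sum(domains$last - domains$first + 1L)
}

#' Domain membership of residue numbers
#'
#' @param residues integer vector of residue numbers
#' @param domains a [domain_map()]
#' @return character vector: domain name per residue, `NA` if outside all
#' @export
assign_domains <- function(residues, domains) {
  stopifnot(inherits(domains, "DomainMap"))
  out <- rep(NA_character_, length(residues))
  for (d in seq_len(nrow(domains))) {
    hit <- residues >= domains$first[d] & residues <= domains$last[d]
    out[hit] <- domains$name[d]
  }
  out
}

#' Total atom count of a solvated simulation system
#'
#' Book-keeping check for an explicit-solvent system: protein and nucleic
#' atoms counted directly, waters counted as molecules times atoms per water
#' (3 for a rigid 3-site model such as TIP3P), plus monatomic counter-ions.
#'
#' @param protein_atoms integer
#' @param dna_atoms integer
#' @param water_molecules integer
#' @param ion_atoms integer
#' @param atoms_per_water integer, default 3
#' @return total atom count
#' @export
system_atom_total <- function(protein_atoms, dna_atoms, water_molecules,
                              ion_atoms, atoms_per_water = 3L) {
  stopifnot(protein_atoms >= 0, dna_atoms >= 0, water_molecules >= 0,
            ion_atoms >= 0, atoms_per_water >= 1)
  protein_atoms + dna_atoms + water_molecules * atoms_per_water + ion_atoms
}
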