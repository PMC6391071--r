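## Crosslinking-MS distance restraint validation: parse residue-pair
## tables, map pairs onto a model with homo-oligomer chain ambiguity,
## measure distances, classify against the DSS-compatible cutoff.

#' Parse a crosslink table
#'
#' CSV with header \code{Protein1,Residue1,Protein2,Residue2} and optional
#' \code{Peptide}/\code{Annotation} columns. Protein names are mapped to
#' chain sets downstream via \code{protein_chain_map}. A transcription of
#' the DSS crosslink table for the helicase-loader complex ships as
#' \code{system.file("extdata", "crosslinks_bp_complex.csv",
#' package = "ringtier")}.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{protein_1}, \code{residue_1},
#'   \code{protein_2}, \code{residue_2}, \code{annotation},
#'   \code{intermolecular} (protein names differ).
#' @export
parseCrosslinkTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(tab) == 0)
    return(data.frame(protein_1 = character(), residue_1 = integer(),
                      protein_2 = character(), residue_2 = integer(),
                      annotation = character(),
                      intermolecular = logical()))
  names(tab) <- tolower(gsub("[ _]", "", names(tab)))
  need <- c("protein1", "residue1", "protein2", "residue2")
  if (!all(need %in% names(tab)))
    stop("crosslink table must have columns Protein1,Residue1,Protein2,Residue2")
  r1 <- suppressWarnings(as.integer(tab$residue1))
  r2 <- suppressWarnings(as.integer(tab$residue2))
  bad <- which(is.na(r1) | is.na(r2) | r1 < 1 | r2 < 1)
  if (length(bad))
    stop("malformed crosslink row(s) (residues must be positive integers): line ",
         paste(bad + 1, collapse = ", "))
  ann <- if ("annotation" %in% names(tab)) tab$annotation
         else if ("peptide" %in% names(tab)) tab$peptide
         else rep("", nrow(tab))
  data.frame(protein_1 = tab$protein1, residue_1 = r1,
             protein_2 = tab$protein2, residue_2 = r2,
             annotation = ann,
             intermolecular = tab$protein1 != tab$protein2,
             stringsAsFactors = FALSE)
}

#' Evaluate crosslink pairs against a model
#'
#' Per pair, the model distance is measured between the chosen atoms
#' (\code{CA} by default: the conventional DSS-compatible bound is ~30 A
#' Ca-Ca; lysine NZ selectable) and classified as satisfied
#' (\code{distance <= cutoff}), violated, or unmapped (no candidate chain
#' pair has both residues modelled). In a homo-oligomer each protein name
#' maps to several chains; with \code{ambiguity = "min_over_chains"} the
#' reported distance is the minimum over all allowed chain pairs, with
#' \code{"fixed_chains"} only the first chain listed per protein is used.
#'
#' @param model a \code{\link{Structure}}.
#' @param pairs data.frame from \code{\link{parseCrosslinkTable}}.
#' @param protein_chain_map named list: protein name -> character vector
#'   of chain ids.
#' @param cutoff distance cutoff, A (default 30, DSS-compatible Ca-Ca).
#' @param atom "CA" or "NZ".
#' @param ambiguity "min_over_chains" or "fixed_chains".
#' @return data.frame: the input pairs plus \code{chain_1}, \code{chain_2}
#'   (best chain pair), \code{distance} (A), \code{status}.
#' @export
evaluateCrosslinks <- function(model, pairs, protein_chain_map,
                               cutoff = 30, atom = c("CA", "NZ"),
                               ambiguity = c("min_over_chains",
                                             "fixed_chains")) {
  atom <- match.arg(atom)
  ambiguity <- match.arg(ambiguity)
  a <- atoms(model)
  a <- a[a$atom == atom, , drop = FALSE]
  if (nrow(a) == 0) stop("model has no '", atom, "' atoms")
  out <- pairs
  out$chain_1 <- NA_character_; out$chain_2 <- NA_character_
  out$distance <- NA_real_; out$status <- "unmapped"
  lookup <- function(protein, resno) {
    chains <- protein_chain_map[[protein]]
    if (is.null(chains)) stop("no chain mapping for protein ", protein)
    if (ambiguity == "fixed_chains") chains <- chains[1]
    a[a$chain %in% chains & a$resno == resno, , drop = FALSE]
  }
  for (i in seq_len(nrow(pairs))) {
    c1 <- lookup(pairs$protein_1[i], pairs$residue_1[i])
    c2 <- lookup(pairs$protein_2[i], pairs$residue_2[i])
    if (nrow(c1) == 0 || nrow(c2) == 0) next
    d <- sqrt(outer(c1$x, c2$x, "-")^2 + outer(c1$y, c2$y, "-")^2 +
              outer(c1$z, c2$z, "-")^2)
    ## same residue on the same chain is a zero self-distance
    k <- arrayInd(which.min(d), dim(d))
    out$chain_1[i] <- c1$chain[k[1]]
    out$chain_2[i] <- c2$chain[k[2]]
    out$distance[i] <- d[k]
    out$status[i] <- if (d[k] <= cutoff) "satisfied" else "violated"
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "atom") <- atom
  attr(out, "ambiguity") <- ambiguity
  out
}

#' Summarise crosslink evaluation results
#'
#' @param results data.frame from \code{\link{evaluateCrosslinks}}.
#' @return list with \code{counts} (named: satisfied/violated/unmapped),
#'   \code{max_distance} (A) and \code{violations} (the violated rows).
#' @export
crosslinkReport <- function(results) {
  counts <- c(satisfied = sum(results$status == "satisfied"),
              violated = sum(results$status == "violated"),
              unmapped = sum(results$status == "unmapped"))
  list(counts = counts,
       max_distance = if (any(!is.na(results$distance)))
         max(results$distance, na.rm = TRUE) else NA_real_,
       violations = results[results$status == "violated", , drop = FALSE])
}
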