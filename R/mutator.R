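## In-silico mutagenesis with side-chain stubs: every substitution
## truncates the side chain to CB and re-labels the residue; a charged
## target places its net charge on CB.  This keeps the charge-deletion
## signal that drives surface-electrostatics comparisons while avoiding
## any rotamer building, and the limitation is recorded in structure
## metadata.  Neutral-to-neutral swaps change labels only.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA", "CB")

#' Define a point mutation
#'
#' @param chain chain identifier.
#' @param res_seq author residue number.
#' @param wt_aa wild-type amino acid (1-letter); checked against the
#'   structure before mutating.
#' @param target_aa target amino acid (1-letter); glycine is not a
#'   supported target (the stub model keeps CB).
#' @return an object of class `"MutationSpec"`.
#' @export
mutation_spec <- function(chain, res_seq, wt_aa, target_aa) {
  wt_aa <- toupper(wt_aa); target_aa <- toupper(target_aa)
  stopifnot(wt_aa %in% AA1)
  if (!target_aa %in% AA1) stop("unknown target amino acid: ", target_aa)
  if (target_aa == "G") {
    stop("glycine is not a supported mutation target (stub model keeps CB)")
  }
  structure(list(chain = chain, res_seq = as.integer(res_seq),
                 wt_aa = wt_aa, target_aa = target_aa),
            class = "MutationSpec")
}

#' Define a named set of mutations
#'
#' @param label set label (e.g. `"T29"`, `"Mutant-VI"`).
#' @param specs list of [mutation_spec()] objects at distinct positions.
#' @return an object of class `"MutantSet"`.
#' @export
mutant_set <- function(label, specs) {
  if (length(specs) > 0) {
    pos <- vapply(specs, function(m) paste(m$chain, m$res_seq), character(1))
    if (anyDuplicated(pos)) stop("mutant set has duplicate positions")
  }
  structure(list(label = label, specs = specs), class = "MutantSet")
}

#' Read mutant sets from a TSV file
#'
#' Expected columns: `label`, `chain`, `pos`, `wt`, `target`; one row
#' per point mutation, grouped into sets by `label`.  Fixtures encoding
#' the published HaeIII directed-evolution panel and the human DNMT2
#' Lys/Arg-to-Ala panel ship with the package under
#' `system.file("extdata", package = "epogram")`.
#'
#' @param path TSV path.
#' @return named list of [mutant_set()] objects, in file order.
#' @export
read_mutant_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("label", "chain", "pos", "wt", "target")
  if (!all(needed %in% names(tab))) {
    stop("mutant TSV must have columns: ", paste(needed, collapse = ", "))
  }
  labels <- unique(tab$label)
  out <- lapply(labels, function(lb) {
    rows <- tab[tab$label == lb, , drop = FALSE]
    mutant_set(lb, lapply(seq_len(nrow(rows)), function(i) {
      mutation_spec(rows$chain[i], as.integer(rows$pos[i]),
                    rows$wt[i], rows$target[i])
    }))
  })
  names(out) <- labels
  out
}

check_mutation <- function(s, spec) {
  a <- s$atoms
  in_res <- which(a$chain == spec$chain & a$res_seq == spec$res_seq)
  if (length(in_res) == 0) {
    return(sprintf("position %s%d not present",
                   trimws(spec$chain), spec$res_seq))
  }
  found <- aa3_to_1(a$res_name[in_res[1]])
  if (found != spec$wt_aa) {
    return(sprintf("wild-type mismatch at %s%d: expected %s, found %s",
                   trimws(spec$chain), spec$res_seq, spec$wt_aa, found))
  }
  if (!all(c("N", "CA", "C") %in% a$name[in_res])) {
    return(sprintf("incomplete backbone at %s%d",
                   trimws(spec$chain), spec$res_seq))
  }
  if (!"CB" %in% a$name[in_res]) {
    ## glycine source lacks CB; the stub model cannot add atoms
    return(sprintf("no CB atom at %s%d (glycine source unsupported)",
                   trimws(spec$chain), spec$res_seq))
  }
  NULL
}

#' Apply a single point mutation (stub model)
#'
#' Removes side-chain atoms beyond CB, renames the residue, and places
#' the target residue's net charge (default table) on CB.  Backbone
#' atoms are untouched.  Returns a modified copy.
#'
#' @param s a `Structure`.
#' @param spec a [mutation_spec()].
#' @param table charge table used for the target's net charge.
#' @return mutated `Structure`.
#' @export
mutate_residue <- function(s, spec, table = default_charge_table()) {
  err <- check_mutation(s, spec)
  if (!is.null(err)) stop(err)
  a <- s$atoms
  in_res <- a$chain == spec$chain & a$res_seq == spec$res_seq
  drop <- in_res & !(a$name %in% BACKBONE_ATOMS)
  a <- a[!drop, , drop = FALSE]
  in_res <- a$chain == spec$chain & a$res_seq == spec$res_seq
  a$res_name[in_res] <- aa1_to_3(spec$target_aa)
  entry <- table$charges[[aa1_to_3(spec$target_aa)]]
  a$charge[in_res] <- 0
  if (!is.null(entry)) {
    cb <- which(in_res & a$name == "CB")
    a$charge[cb[1]] <- entry$q
  }
  out <- s
  out$atoms <- a
  rownames(out$atoms) <- NULL
  out
}

#' Apply a mutant set
#'
#' All specs are validated first; any failure aborts with a message
#' listing every failing spec (no partial mutant is returned).
#' Mutations are applied in ascending residue number; the result is
#' independent of listed order because positions are distinct.
#'
#' @param s a `Structure` (wild type).
#' @param m a [mutant_set()].
#' @param table charge table (see [mutate_residue()]).
#' @return mutated `Structure`, with `id` suffixed by the set label.
#' @export
apply_mutant_set <- function(s, m, table = default_charge_table()) {
  errs <- Filter(Negate(is.null), lapply(m$specs, function(sp) {
    check_mutation(s, sp)
  }))
  if (length(errs) > 0) {
    stop(sprintf("mutant set '%s' cannot be applied:\n  %s", m$label,
                 paste(unlist(errs), collapse = "\n  ")))
  }
  ord <- order(vapply(m$specs, `[[`, integer(1), "res_seq"))
  out <- s
  for (sp in m$specs[ord]) out <- mutate_residue(out, sp, table)
  if (length(m$specs) > 0) out$id <- paste(s$id, m$label, sep = "_")
  out
}
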