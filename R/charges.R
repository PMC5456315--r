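## Reduced charge model: one net point charge per ionizable residue at a
## canonical side-chain atom, all other atoms neutral, per-element radii.
## Full per-atom charge sets enter the pipeline through PQR input with
## assign_charges(mode = "keep").

#' Default charge/radius table
#'
#' The reduced model places one net point charge per ionizable residue:
#' Arg +1 on CZ, Lys +1 on NZ, Asp -1 on CG, Glu -1 on CD; His is
#' neutral by default.  Radii are per-element (C 1.7, N 1.55, O 1.52,
#' S 1.8, H 1.2 Angstrom; anything else 1.7).  Each charge entry lists
#' its site atoms in priority order; by default only the canonical atom
#' is accepted (see the `fallback` argument of [assign_charges()]).
#'
#' @return a list of class `"ChargeRadiusTable"` with elements `charges`
#'   (per-residue site atom and net charge) and `radii` (per element).
#' @export
default_charge_table <- function() {
  structure(list(
    charges = list(
      ARG = list(site = "CZ", q = +1),
      LYS = list(site = "NZ", q = +1),
      ASP = list(site = "CG", q = -1),
      GLU = list(site = "CD", q = -1)
    ),
    radii = c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2),
    default_radius = 1.7
  ), class = "ChargeRadiusTable")
}

residue_net_charge <- function(res_name, table = default_charge_table()) {
  vapply(res_name, function(r) {
    e <- table$charges[[toupper(r)]]
    if (is.null(e)) 0 else e$q
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assign partial charges and radii to a structure
#'
#' Under the default reduced model exactly one atom per charged residue
#' (Arg, Lys, Asp, Glu) carries the residue's net charge at its
#' canonical side-chain site; all other charges are zero.  Radii are
#' filled from the per-element table wherever unset.  With
#' `mode = "keep"` existing (e.g. PQR-sourced) charges are preserved and
#' only missing radii are filled.
#'
#' `fallback = "cb"` permits the net charge to sit on CB when the
#' canonical site atom is absent — the convention used for side-chain
#' stub models (mutants, synthetic helices).  The default
#' (`fallback = "none"`) treats a missing site atom as an error.
#'
#' @param s a `Structure`.
#' @param table a [default_charge_table()]-style table.
#' @param mode `"reduced"` (default) or `"keep"`.
#' @param fallback `"none"` (default) or `"cb"`.
#' @param ionize_termini add +1 to the first residue's N and -1 to the
#'   last residue's C (or OXT if present) per chain; default `FALSE`.
#' @return a copy of `s` with `charge` and `radius` populated.
#' @export
assign_charges <- function(s, table = default_charge_table(),
                           mode = c("reduced", "keep"),
                           fallback = c("none", "cb"),
                           ionize_termini = FALSE) {
  mode <- match.arg(mode)
  fallback <- match.arg(fallback)
  a <- s$atoms
  fill <- is.na(a$radius)
  a$radius[fill] <- table$radii[a$element[fill]]
  a$radius[is.na(a$radius)] <- table$default_radius
  if (mode == "reduced") {
    a$charge <- 0
    rt <- residue_table(s)
    missing <- character(0)
    for (i in seq_len(nrow(rt))) {
      entry <- table$charges[[toupper(rt$res_name[i])]]
      if (is.null(entry)) next
      in_res <- which(a$chain == rt$chain[i] & a$res_seq == rt$res_seq[i])
      sites <- entry$site
      if (fallback == "cb") sites <- c(sites, "CB")
      hit <- in_res[match(sites, a$name[in_res])]
      hit <- hit[!is.na(hit)]
      if (length(hit) == 0) {
        missing <- c(missing, sprintf("%s %s%d", rt$res_name[i],
                                      trimws(rt$chain[i]), rt$res_seq[i]))
      } else {
        a$charge[hit[1]] <- entry$q
      }
    }
    if (length(missing) > 0) {
      stop("charge-site atom missing for residue(s): ",
           paste(missing, collapse = "; "))
    }
    if (ionize_termini) {
      for (ch in unique(a$chain)) {
        in_ch <- which(a$chain == ch & !a$het)
        first <- a$res_seq[in_ch[1]]
        last <- a$res_seq[in_ch[length(in_ch)]]
        nt <- in_ch[a$res_seq[in_ch] == first & a$name[in_ch] == "N"]
        ct <- in_ch[a$res_seq[in_ch] == last &
                      a$name[in_ch] %in% c("OXT", "C")]
        ct <- ct[order(match(a$name[ct], c("OXT", "C")))]
        if (length(nt) > 0) a$charge[nt[1]] <- a$charge[nt[1]] + 1
        if (length(ct) > 0) a$charge[ct[1]] <- a$charge[ct[1]] - 1
      }
    }
  }
  out <- s
  out$atoms <- a
  out
}

#' Total charge of a structure
#'
#' @param s a `Structure` (charges assigned).
#' @return net charge in elementary-charge units.
#' @export
net_charge <- function(s) {
  if (n_atoms(s) == 0) return(0)
  q <- sum(s$atoms$charge)
  chargeable <- any(toupper(s$atoms$res_name) %in%
                      c("ARG", "LYS", "ASP", "GLU"))
  if (q == 0 && all(s$atoms$charge == 0) && chargeable) {
    warning("all atom charges are zero; did you run assign_charges()?")
  }
  q
}
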