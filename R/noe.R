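#' State-labelled NOE contact tables
#'
#' A `noe_contacts` object is a data frame of through-space proton-proton
#' (or pseudo-atom) correlations, one row per contact: `res1`, `atom1`,
#' `state1`, `res2`, `atom2`, `state2`, `intensity` (arbitrary units,
#' >= 0) and `intermolecular`. States are `"A"`, `"B"` or `"unknown"`;
#' classification requires both ends of intermolecular contacts to carry a
#' defined state.
#'
#' @param contacts data frame with the columns above (`intensity` defaults
#'   to 1, `intermolecular` to TRUE).
#' @return A `noe_contacts` object.
#' @export
noe_contacts <- function(contacts) {
  need <- c("res1", "atom1", "state1", "res2", "atom2", "state2")
  miss <- setdiff(need, names(contacts))
  if (length(miss)) stop_ad("contacts missing columns: ",
                            paste(miss, collapse = ", "))
  df <- as.data.frame(contacts)
  if (is.null(df$intensity)) df$intensity <- rep(1, nrow(df))
  if (is.null(df$intermolecular)) df$intermolecular <- rep(TRUE, nrow(df))
  df <- df[c(need, "intensity", "intermolecular")]
  for (col in c("state1", "state2")) {
    df[[col]] <- as.character(df[[col]])
    if (!all(df[[col]] %in% c("A", "B", "unknown")))
      stop_ad(col, " must be 'A', 'B' or 'unknown'")
  }
  if (any(df$intensity < 0)) stop_ad("intensity must be >= 0")
  structure(df, class = c("noe_contacts", "data.frame"))
}

#' @export
print.noe_contacts <- function(x, ...) {
  cat(sprintf("noe_contacts: %d contacts (%d intermolecular)\n",
              nrow(x), sum(x$intermolecular)))
  NextMethod()
}

#' Classify homodimer topology from state-labelled intermolecular NOEs
#'
#' In a symmetric homodimer both subunits are in the same conformational
#' state, so intermolecular NOEs connect like states only (A-A or B-B); an
#' asymmetric homodimer pairs one subunit in each state, so intermolecular
#' NOEs connect unlike states (A-B). `strict` mode (default) demands
#' unanimity and reports `"ambiguous"` for mixtures; `majority` votes by
#' count and reports the margin.
#'
#' @param contacts a [noe_contacts] table; only intermolecular contacts
#'   with both states labelled are informative.
#' @param mode `"strict"` or `"majority"`.
#' @return A `dimer_call`: list with `verdict` (`"symmetric"`,
#'   `"asymmetric"` or `"ambiguous"`), `n_same_state`, `n_cross_state`,
#'   `margin` (majority mode) and `supporting` (the informative contacts).
#' @export
classify_dimer <- function(contacts, mode = c("strict", "majority")) {
  mode <- match.arg(mode)
  stopifnot(inherits(contacts, "noe_contacts"))
  use <- contacts$intermolecular & contacts$state1 != "unknown" &
    contacts$state2 != "unknown"
  if (!any(use))
    stop_ad("uninformative: no state-labelled intermolecular contacts")
  inf <- contacts[use, , drop = FALSE]
  cross <- inf$state1 != inf$state2
  n_cross <- sum(cross)
  n_same <- sum(!cross)
  verdict <- if (mode == "strict") {
    if (n_cross > 0 && n_same == 0) "asymmetric"
    else if (n_same > 0 && n_cross == 0) "symmetric"
    else "ambiguous"
  } else {
    if (n_cross > n_same) "asymmetric"
    else if (n_same > n_cross) "symmetric"
    else "ambiguous"
  }
  structure(list(verdict = verdict, n_same_state = n_same,
                 n_cross_state = n_cross, mode = mode,
                 margin = abs(n_cross - n_same), supporting = inf),
            class = "dimer_call")
}

#' @export
print.dimer_call <- function(x, ...) {
  cat(sprintf("dimer_call (%s): %s (%d cross-state, %d same-state contacts)\n",
              x$mode, x$verdict, x$n_cross_state, x$n_same_state))
  invisible(x)
}

# Proton / pseudo-atom selection: amide H plus Q* pseudo-atoms.
proton_like <- function(at) at$element == "H" | startsWith(at$atom, "Q")

# All proton-pair contacts within the (pseudo-corrected) cutoff.
enumerate_noe_pairs <- function(s, cutoff, intermolecular_only = TRUE,
                                pseudo_extra = 1.0) {
  stopifnot(inherits(s, "structure3d"))
  at <- s$atoms
  sel <- which(proton_like(at))
  if (!length(sel))
    stop_ad("structure has no protons or pseudo-atoms")
  if (intermolecular_only && length(unique(at$chain)) < 2) {
    warn_ad("single chain: no intermolecular contacts possible")
    return(cbind(at[integer(0), ], data.frame(distance = numeric(0))))
  }
  xyz <- coords(s, sel)
  D <- as.matrix(stats::dist(xyz))
  pseudo <- startsWith(at$atom[sel], "Q")
  eff <- cutoff + pseudo_extra * outer(pseudo, pseudo, "|")
  keep <- upper.tri(D) & D <= eff
  if (intermolecular_only)
    keep <- keep & outer(at$chain[sel], at$chain[sel], "!=")
  else
    keep <- keep & !(outer(at$chain[sel], at$chain[sel], "==") &
                     outer(at$seqnum[sel], at$seqnum[sel], "=="))
  idx <- which(keep, arr.ind = TRUE)
  i1 <- sel[idx[, 1]]; i2 <- sel[idx[, 2]]
  data.frame(chain1 = at$chain[i1], res1 = at$seqnum[i1],
             atom1 = at$atom[i1],
             chain2 = at$chain[i2], res2 = at$seqnum[i2],
             atom2 = at$atom[i2],
             distance = D[idx])
}

label_noe_states <- function(pairs, state_of_chain) {
  if (is.null(names(state_of_chain)))
    stop_ad("state_of_chain must be a named chain -> state vector")
  df <- pairs
  df$state1 <- unname(state_of_chain[df$chain1])
  df$state2 <- unname(state_of_chain[df$chain2])
  df$state1[is.na(df$state1)] <- "unknown"
  df$state2[is.na(df$state2)] <- "unknown"
  # arbitrary-unit intensity with the r^-6 distance dependence of the NOE
  df$intensity <- (2 / pmax(df$distance, 2))^6
  df$intermolecular <- df$chain1 != df$chain2
  out <- noe_contacts(df)
  out$distance <- df$distance
  out$chain1 <- df$chain1
  out$chain2 <- df$chain2
  out
}

#' Predict intermolecular NOE contacts from a structure
#'
#' Enumerates all inter-chain proton/pseudo-atom pairs within the cutoff
#' (plus a 1 Angstrom pseudo-atom correction for Q* atoms) and labels each
#' endpoint with its chain's conformational state. Any contact list
#' observed in the filtered experiment at the same cutoff must be a subset
#' of this prediction.
#'
#' @param s a two-chain [structure3d] with protons/pseudo-atoms.
#' @param state_of_chain named chain -> state map, e.g. `c(A = "A", B = "B")`.
#' @param cutoff distance cutoff, Angstrom.
#' @return A [noe_contacts] table with `distance` column.
#' @export
predict_intermolecular_noes <- function(s, state_of_chain, cutoff = 5.5) {
  if (!is_number(cutoff) || cutoff <= 0) stop_ad("cutoff must be > 0")
  pairs <- enumerate_noe_pairs(s, cutoff, intermolecular_only = TRUE)
  if (!nrow(pairs)) {
    out <- noe_contacts(data.frame(res1 = integer(), atom1 = character(),
                                   state1 = character(), res2 = integer(),
                                   atom2 = character(), state2 = character()))
    out$distance <- numeric(0)
    return(out)
  }
  label_noe_states(pairs, state_of_chain)
}

#' Validate NOE contacts against a structural model
#'
#' Maps each contact endpoint onto the structure through the chain-state
#' assignment (state A lives on the chain mapped to A, and so on), measures
#' the distance, and flags the contact satisfied when it is within the
#' cutoff (plus 1 Angstrom per pseudo-atom endpoint). For every satisfied
#' cross-state contact (i_A, j_B) the mirror contact (i_B, j_A) is also
#' measured: in an asymmetric dimer the mirror is violated, which is the
#' structural signature distinguishing it from a symmetric one.
#'
#' @param contacts a [noe_contacts] table.
#' @param s a [structure3d].
#' @param state_of_chain named chain -> state map.
#' @param cutoff distance cutoff, Angstrom.
#' @return List with `details` (per-contact distance, satisfied and mapped
#'   flags), `fraction_satisfied` (over mapped contacts), and `mirror`
#'   (per satisfied cross-state contact, the mirror distance and whether
#'   the mirror is violated).
#' @export
validate_against_structure <- function(contacts, s, state_of_chain,
                                       cutoff = 5.5) {
  stopifnot(inherits(contacts, "noe_contacts"), inherits(s, "structure3d"))
  chain_of_state <- stats::setNames(names(state_of_chain),
                                    unname(state_of_chain))
  at <- s$atoms
  find_atom <- function(state, res, atom) {
    ch <- chain_of_state[state]
    if (is.na(ch)) return(NULL)
    hit <- which(at$chain == ch & at$seqnum == res & at$atom == toupper(atom))
    if (length(hit) != 1L) NULL else as.numeric(at[hit, c("x", "y", "z")])
  }
  dist_of <- function(s1, r1, a1, s2, r2, a2) {
    p1 <- find_atom(s1, r1, a1)
    p2 <- find_atom(s2, r2, a2)
    if (is.null(p1) || is.null(p2)) NA_real_ else sqrt(sum((p1 - p2)^2))
  }
  eff_cut <- cutoff + 1.0 * (startsWith(contacts$atom1, "Q") |
                             startsWith(contacts$atom2, "Q"))
  d <- mapply(dist_of, contacts$state1, contacts$res1, contacts$atom1,
              contacts$state2, contacts$res2, contacts$atom2)
  details <- data.frame(contacts[, c("res1", "atom1", "state1", "res2",
                                     "atom2", "state2")],
                        distance = d, mapped = !is.na(d),
                        satisfied = !is.na(d) & d <= eff_cut)
  if (any(!details$mapped))
    warn_ad(sum(!details$mapped), " contact(s) could not be mapped")
  mir_rows <- which(details$satisfied & contacts$state1 != contacts$state2 &
                    contacts$state1 != "unknown" &
                    contacts$state2 != "unknown")
  mirror <- do.call(rbind, lapply(mir_rows, function(i) {
    md <- dist_of(contacts$state2[i], contacts$res1[i], contacts$atom1[i],
                  contacts$state1[i], contacts$res2[i], contacts$atom2[i])
    data.frame(res1 = contacts$res1[i], atom1 = contacts$atom1[i],
               res2 = contacts$res2[i], atom2 = contacts$atom2[i],
               distance = details$distance[i], mirror_distance = md,
               mirror_violated = is.na(md) | md > eff_cut[i])
  }))
  list(details = details,
       fraction_satisfied = if (any(details$mapped))
         mean(details$satisfied[details$mapped]) else NA_real_,
       mirror = mirror %||% data.frame())
}

#' Read/write NOE contact tables
#'
#' Tab-separated with header
#' `res1 atom1 state1 res2 atom2 state2 intensity`; comment lines prefixed
#' `#` are ignored.
#'
#' @param path file path.
#' @return [noe_contacts] (reader) or `path` invisibly (writer).
#' @export
read_noe_table <- function(path) {
  if (!file.exists(path)) stop_ad("no such file: ", path)
  df <- utils::read.delim(path, comment.char = "#")
  noe_contacts(df)
}

#' @rdname read_noe_table
#' @param contacts a [noe_contacts] table.
#' @export
write_noe_table <- function(contacts, path) {
  df <- contacts[c("res1", "atom1", "state1", "res2", "atom2", "state2",
                   "intensity")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}
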