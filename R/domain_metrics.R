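#' Absolute contact order
#'
#' Mean sequence separation |j - i| over a contact subset — a measure of
#' fold complexity that anti-correlates with folding rate. Separations are
#' taken in the numbering of the chain the contacts are expressed in, so a
#' circular permutation (which renumbers the chain) changes the ACO even
#' though the 3-D contact set is unchanged.
#'
#' @param contacts a [contact_map] or data.frame with columns i, j.
#' @export
absolute_contact_order <- function(contacts) {
  if (nrow(contacts) == 0) stop("contact subset is empty")
  mean(contacts$j - contacts$i)
}

#' Packing fraction
#'
#' Contacts per residue at the C-alpha level (typically 2.0-3.0 for
#' well-packed domains).
#'
#' @param contacts contact subset.
#' @param n_residues number of residues the subset is normalized by.
#' @export
packing_fraction <- function(contacts, n_residues) {
  stopifnot(n_residues >= 1)
  nrow(contacts) / n_residues
}

#' Per-domain structural metrics
#'
#' For each domain of a partition: the absolute contact order and packing
#' fraction over the contacts internal to the domain (both residues inside
#' it), and the chain length as the sum of its interval lengths (residue
#' count, not span).
#'
#' @param cmap a [contact_map], labelled or not (labels are recomputed).
#' @param partition a [domain_partition].
#' @return data.frame with columns `domain`, `ACO`, `L`, `rho`.
#' @export
domain_metrics <- function(cmap, partition) {
  cmap <- classify_contacts(cmap, partition)
  out <- lapply(names(partition), function(nm) {
    sub <- cmap[!is.na(cmap$label) & cmap$label == paste0("intra:", nm), , drop = FALSE]
    L <- sum(partition[[nm]][, 2] - partition[[nm]][, 1] + 1)
    data.frame(domain = nm,
               ACO = if (nrow(sub) > 0) absolute_contact_order(sub) else NA_real_,
               L = L, rho = packing_fraction(sub, L))
  })
  do.call(rbind, out)
}

#' Compare an inserted domain with its discontinuous host
#'
#' Computes ACO, chain length and packing fraction separately for the
#' inserted domain and the discontinuous domain it sits in (contacts
#' internal to each domain only) and flags, for each metric, whether the
#' discontinuous domain's value is strictly higher.
#'
#' @param cmap a [contact_map].
#' @param partition a [domain_partition].
#' @param inserted,discontinuous domain names; the inserted domain must
#'   actually be inserted (its span strictly inside another domain's span).
#' @return an `insert_comparison`: the two metric rows plus logical flags
#'   `aco_higher`, `length_higher`, `rho_higher`, `all_three`.
#' @export
compare_insert_pair <- function(cmap, partition, inserted, discontinuous) {
  stopifnot(inserted %in% names(partition), discontinuous %in% names(partition))
  if (!domain_is_inserted(partition, inserted))
    stop(sprintf("domain '%s' is not inserted within another domain", inserted))
  m <- domain_metrics(cmap, partition)
  x <- m[m$domain == inserted, ]
  y <- m[m$domain == discontinuous, ]
  flags <- list(aco_higher = isTRUE(y$ACO > x$ACO),
                length_higher = isTRUE(y$L > x$L),
                rho_higher = isTRUE(y$rho > x$rho))
  flags$all_three <- flags$aco_higher && flags$length_higher && flags$rho_higher
  structure(list(inserted = x, discontinuous = y, flags = flags),
            class = "insert_comparison")
}

#' @export
print.insert_comparison <- function(x, ...) {
  cat(sprintf("insert pair: %s (inserted) vs %s (discontinuous)\n",
              x$inserted$domain, x$discontinuous$domain))
  cat(sprintf("  ACO %.2f vs %.2f | L %d vs %d | rho %.2f vs %.2f\n",
              x$inserted$ACO, x$discontinuous$ACO, x$inserted$L,
              x$discontinuous$L, x$inserted$rho, x$discontinuous$rho))
  cat(sprintf("  discontinuous higher: ACO %s, length %s, rho %s; all three: %s\n",
              x$flags$aco_higher, x$flags$length_higher, x$flags$rho_higher,
              x$flags$all_three))
  invisible(x)
}

#' Flag functional sites that span a domain interface
#'
#' A functional site (set of residues) spans the interface between two
#' domains when it contains at least one residue in each; the overall flag
#' is true when any site spans.
#'
#' @param functional_sites list of residue index vectors (non-empty).
#' @param partition a [domain_partition].
#' @param domA,domB the two domain names.
#' @param n_residues chain length, for validating site residues.
#' @return list with `per_site` (logical vector) and `any_spans`.
#' @export
interface_function_flag <- function(functional_sites, partition, domA, domB,
                                    n_residues) {
  if (length(functional_sites) == 0) stop("no functional sites supplied")
  dom <- residue_domains(partition, n_residues)
  per_site <- vapply(functional_sites, function(site) {
    if (any(site < 1 | site > n_residues))
      stop("functional-site residue outside the chain")
    d <- dom[site]
    (domA %in% d) && (domB %in% d)
  }, logical(1))
  list(per_site = per_site, any_spans = any(per_site))
}
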