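#' Fragment distinction flags
#'
#' Which atomic and bond properties enter a fragment's identity: `A` atom
#' element (aromatic carbon is distinguished from aliphatic), `B` bond order
#' (aromatic bonds form their own class), `C` heavy-atom connectivity in the
#' parent molecule, `H` attached hydrogen count, `DA` donor/acceptor class
#' (donor = N/O with at least one hydrogen; acceptor = N/O without positive
#' formal charge).
#'
#' @param A,B,C,H,DA Logical flags; at least one must be `TRUE`.
#' @return An object of class `distinction_flags`.
#' @export
distinction_flags <- function(A = TRUE, B = FALSE, C = FALSE,
                              H = FALSE, DA = FALSE) {
  flags <- c(A = isTRUE(A), B = isTRUE(B), C = isTRUE(C),
             H = isTRUE(H), DA = isTRUE(DA))
  if (!any(flags)) stop("at least one distinction flag must be set")
  structure(as.list(flags), class = "distinction_flags")
}

#' @export
format.distinction_flags <- function(x, ...) {
  on <- names(x)[vapply(x, isTRUE, logical(1))]
  paste(sub("^DA$", "D&A", on), collapse = "/")
}

#' @export
print.distinction_flags <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Enumerate connected molecular fragments
#'
#' Every connected induced subgraph of the heavy-atom graph with atom count
#' in `[min_atoms, max_atoms]`, each distinct atom set counted exactly once
#' (so linear, branched, cyclic, and overlapping fragments are all covered).
#' Uses the ESU (exclusive-neighborhood) enumeration scheme, which emits each
#' subgraph once without an explicit duplicate check.
#'
#' @param mol A [parse_smiles()] molecule.
#' @param min_atoms,max_atoms Fragment size bounds; `max_atoms <= 12`.
#' @return A list of integer atom-index vectors (sorted within each
#'   fragment).
#' @export
enumerate_fragments <- function(mol, min_atoms, max_atoms) {
  stopifnot(inherits(mol, "molecule"), min_atoms >= 1, min_atoms <= max_atoms)
  if (max_atoms > 12L) stop("max_atoms > 12 exceeds the combinatorial guard")
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol)
  out <- vector("list", 0L)
  emit <- function(S) out[[length(out) + 1L]] <<- sort(S)

  extend <- function(S, ext, v) {
    if (length(S) >= min_atoms) emit(S)
    if (length(S) == max_atoms) return(invisible())
    while (length(ext)) {
      w <- ext[1L]; ext <- ext[-1L]
      nbhd <- unique(unlist(adj[S], use.names = FALSE))
      new_ext <- setdiff(adj[[w]], c(S, nbhd))
      new_ext <- new_ext[new_ext > v]
      extend(c(S, w), c(ext, new_ext), v)
    }
  }
  for (v in seq_len(n)) {
    ext0 <- adj[[v]][adj[[v]] > v]
    extend(v, ext0, v)
  }
  out
}

atom_labels <- function(mol, flags) {
  da <- if (flags$DA) donor_acceptor_class(mol) else NULL
  n <- nrow(mol$atoms)
  vapply(seq_len(n), function(i) {
    parts <- character(0)
    if (flags$A) {
      el <- mol$atoms$element[i]
      if (mol$atoms$aromatic[i]) el <- tolower(el)
      if (mol$atoms$charge[i] != 0L)
        el <- paste0(el, sprintf("%+d", mol$atoms$charge[i]))
      parts <- c(parts, el)
    }
    if (flags$C) parts <- c(parts, paste0("c", mol$atoms$degree[i]))
    if (flags$H) parts <- c(parts, paste0("h", mol$atoms$h_count[i]))
    if (flags$DA) parts <- c(parts, da[i])
    paste(parts, collapse = ";")
  }, character(1))
}

bond_labels <- function(mol, flags) {
  if (!nrow(mol$bonds)) return(character(0))
  if (!flags$B) return(rep("~", nrow(mol$bonds)))
  ifelse(mol$bonds$aromatic, "a", as.character(mol$bonds$order))
}

#' Canonical fragment key
#'
#' A string identifying a fragment up to atom renumbering, built from exactly
#' the properties whose [distinction_flags()] are set. Canonicalization is
#' Morgan-style: iterative neighborhood refinement of atom colors, followed
#' by backtracking individualization of tied atoms; the lexicographically
#' smallest labelling over all branches defines the key.
#'
#' @param mol A [parse_smiles()] molecule.
#' @param atom_ids Integer atom indices of a connected fragment.
#' @param flags A [distinction_flags()] object.
#' @return A canonical key string.
#' @export
fragment_key <- function(mol, atom_ids, flags = distinction_flags()) {
  stopifnot(inherits(mol, "molecule"), inherits(flags, "distinction_flags"))
  atom_ids <- sort(unique(as.integer(atom_ids)))
  k <- length(atom_ids)
  labels <- atom_labels(mol, flags)[atom_ids]
  keep <- mol$bonds$a1 %in% atom_ids & mol$bonds$a2 %in% atom_ids
  blab_all <- bond_labels(mol, flags)
  b1 <- match(mol$bonds$a1[keep], atom_ids)
  b2 <- match(mol$bonds$a2[keep], atom_ids)
  blab <- blab_all[keep]
  canonical_graph_key(k, labels, b1, b2, blab)
}

# Canonical labelling of a small vertex/edge-labelled graph by refinement
# with backtracking over remaining symmetric classes.
canonical_graph_key <- function(k, labels, b1, b2, blab) {
  if (k == 1L) return(paste0("(", labels, ")"))
  adj <- vector("list", k)
  edge_lab <- vector("list", k)
  for (e in seq_along(b1)) {
    adj[[b1[e]]] <- c(adj[[b1[e]]], b2[e])
    adj[[b2[e]]] <- c(adj[[b2[e]]], b1[e])
    edge_lab[[b1[e]]] <- c(edge_lab[[b1[e]]], blab[e])
    edge_lab[[b2[e]]] <- c(edge_lab[[b2[e]]], blab[e])
  }
  refine <- function(color) {
    repeat {
      sig <- vapply(seq_len(k), function(i) {
        nb <- paste(sort(paste0(edge_lab[[i]], ":", color[adj[[i]]])),
                    collapse = ",")
        paste0(color[i], "|", nb)
      }, character(1))
      new_color <- match(sig, sort(unique(sig)))
      if (identical(new_color, color)) return(color)
      color <- new_color
    }
  }
  string_for <- function(order_idx) {
    pos <- integer(k); pos[order_idx] <- seq_len(k)
    edges <- sort(vapply(seq_along(b1), function(e) {
      i <- pos[b1[e]]; j <- pos[b2[e]]
      sprintf("%d-%d:%s", min(i, j), max(i, j), blab[e])
    }, character(1)))
    paste(paste(labels[order_idx], collapse = "."),
          paste(edges, collapse = "."), sep = "/")
  }
  best <- NULL
  descend <- function(color) {
    color <- refine(color)
    tab <- table(color)
    if (all(tab == 1L)) {
      cand <- string_for(order(color))
      if (is.null(best) || cand < best) best <<- cand
      return(invisible())
    }
    cls <- as.integer(names(tab)[tab > 1L])[1L]
    members <- which(color == cls)
    for (m in members) {
      c2 <- color
      c2[m] <- 0L   # individualize: strictly smallest color
      c2 <- match(c2, sort(unique(c2)))
      descend(c2)
    }
  }
  init <- match(labels, sort(unique(labels)))
  descend(init)
  best
}

# table-driven CRC-32 (IEEE 802.3 polynomial), for hashing fragment keys
crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (i in 0:255) {
      c <- i
      for (j in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L)
          bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320 as signed
        else bitwShiftR(c, 1L)
      }
      t[i + 1L] <- c
    }
    tab <<- t
    tab
  }
})

#' CRC-32 checksum of a string
#'
#' Standard IEEE CRC-32, returned as a double in `[0, 2^32)`.
#'
#' @param x A single character string.
#' @return The checksum as a double.
#' @export
crc32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tab <- crc32_table()
  bytes <- as.integer(charToRaw(x))
  c <- -1L  # 0xFFFFFFFF
  for (b in bytes) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(bitwShiftR(c, 8L), tab[idx + 1L])
  }
  c <- bitwXor(c, -1L)
  if (c < 0) c + 4294967296 else as.numeric(c)
}

# session-level caches: canonical fragment keys are expensive, and grid
# searches revisit the same molecule under many hologram lengths (the keys do
# not depend on the length) — so keys are cached per molecule content,
# distinction flags, and size range, and CRC values per key string.
.frag_cache <- new.env(parent = emptyenv())
.crc_cache <- new.env(parent = emptyenv())

mol_signature <- function(mol) {
  paste(
    paste(mol$atoms$element, as.integer(mol$atoms$aromatic),
          mol$atoms$charge, mol$atoms$h_count, collapse = ";"),
    paste(mol$bonds$a1, mol$bonds$a2, mol$bonds$order,
          as.integer(mol$bonds$aromatic), collapse = ";"),
    sep = "#"
  )
}

crc32_cached <- function(key) {
  hit <- .crc_cache[[key]]
  if (!is.null(hit)) return(hit)
  v <- crc32(key)
  .crc_cache[[key]] <- v
  v
}

# enumerate fragments and canonical keys, cached per molecule/flags/sizes
fragment_occurrences <- function(mol, flags, min_atoms, max_atoms) {
  cache_key <- paste(mol_signature(mol), format(flags), min_atoms, max_atoms)
  hit <- .frag_cache[[cache_key]]
  if (!is.null(hit)) return(hit)
  frags <- enumerate_fragments(mol, min_atoms, max_atoms)
  keys <- vapply(frags, function(f) fragment_key(mol, f, flags), character(1))
  out <- list(frags = frags, keys = keys)
  .frag_cache[[cache_key]] <- out
  out
}

#' Build a molecular hologram
#'
#' Enumerates all fragments of the molecule in the configured size range,
#' keys each occurrence canonically under the distinction flags, and
#' increments `counts[crc32(key) mod length + 1]` once per occurrence. The
#' total count equals the number of enumerated fragment occurrences.
#'
#' @param mol A [parse_smiles()] molecule.
#' @param length Hologram length (conventionally a prime such as 53, 59, 61,
#'   71, 83, 97, 151, 199, 257, 307, 353, 401).
#' @param flags A [distinction_flags()] object.
#' @param min_atoms,max_atoms Fragment size range.
#' @return An object of class `hologram`: list with `length`, `counts`
#'   (integer vector), and `fragment_index` (named integer vector: canonical
#'   key -> bin).
#' @export
build_hologram <- function(mol, length = 83L, flags = distinction_flags(),
                           min_atoms = 4L, max_atoms = 7L) {
  occ <- fragment_occurrences(mol, flags, min_atoms, max_atoms)
  counts <- integer(length)
  bin_of <- vapply(unique(occ$keys), function(k)
    as.integer(crc32_cached(k) %% length) + 1L, integer(1))
  for (k in occ$keys) counts[bin_of[[k]]] <- counts[bin_of[[k]]] + 1L
  structure(list(length = as.integer(length), counts = counts,
                 fragment_index = bin_of),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("hologram: length %d, %d occurrences in %d occupied bins\n",
              x$length, sum(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Hologram matrix for a molecule set
#'
#' @param mols List of [parse_smiles()] molecules.
#' @inheritParams build_hologram
#' @return Integer matrix, molecules x bins.
#' @export
hologram_matrix <- function(mols, length = 83L, flags = distinction_flags(),
                            min_atoms = 4L, max_atoms = 7L) {
  rows <- lapply(mols, function(m)
    build_hologram(m, length, flags, min_atoms, max_atoms)$counts)
  do.call(rbind, rows)
}
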