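#' Parse a SMILES string into a molecular graph
#'
#' A compact SMILES reader covering the organic subset (B, C, N, O, P, S, F,
#' Cl, Br, I and aromatic b, c, n, o, p, s), bracket atoms with explicit
#' hydrogen counts and formal charges, branches, ring closures (including
#' `%nn`), and bond symbols `-`, `=`, `#`, `:`. Aromatic bonds are kept as
#' their own bond class (never kekulized), so fragment keys and holograms do
#' not depend on how an aromatic ring happens to be written. Implicit
#' hydrogens follow the standard valence rules (bracket atoms carry exactly
#' the hydrogens they declare).
#'
#' @param smiles A single SMILES string (no disconnected components).
#' @return An object of class `molecule`: list with `atoms` (data.frame:
#'   `element`, `aromatic`, `charge`, `h_count`, `degree`), `bonds`
#'   (data.frame: `a1`, `a2`, `order`, `aromatic`), and `smiles`.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "")[[1L]]
  n_ch <- length(chars)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  stack <- integer(0)
  pending_bond <- NA_character_
  ring <- list()   # ring number -> list(atom, bond)
  i <- 1L

  add_atom <- function(element, aromatic, charge = 0L, h_explicit = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge, h_explicit = h_explicit)
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    ar_a <- atoms[[a]]$aromatic; ar_b <- atoms[[b]]$aromatic
    if (is.na(sym)) {
      aromatic <- ar_a && ar_b
      order <- 1L
    } else if (sym == ":") {
      aromatic <- TRUE; order <- 1L
    } else {
      aromatic <- FALSE
      order <- switch(sym, "-" = 1L, "=" = 2L, "#" = 3L,
                      stop("unsupported bond symbol: ", sym))
    }
    bonds[[length(bonds) + 1L]] <<- list(a1 = min(a, b), a2 = max(a, b),
                                         order = order, aromatic = aromatic)
  }

  while (i <= n_ch) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":")) {
      pending_bond <- ch; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending_bond <- "-"; i <- i + 1L   # stereo bonds read as single
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      stop("disconnected SMILES (dot) not supported: ", smiles)
    } else if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        if (i + 2L > n_ch) stop("truncated %nn ring closure")
        num <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else {
        num <- ch; i <- i + 1L
      }
      if (is.na(prev)) stop("ring closure before any atom")
      if (is.null(ring[[num]])) {
        ring[[num]] <- list(atom = prev, bond = pending_bond)
      } else {
        open <- ring[[num]]
        sym <- if (!is.na(pending_bond)) pending_bond else open$bond
        add_bond(open$atom, prev, sym)
        ring[[num]] <- NULL
      }
      pending_bond <- NA_character_
    } else if (ch == "[") {
      close <- i
      while (close <= n_ch && chars[close] != "]") close <- close + 1L
      if (close > n_ch) stop("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$h)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NA_character_
      prev <- idx
      i <- close + 1L
    } else {
      two <- if (i < n_ch) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, FALSE); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        idx <- add_atom(ch, FALSE); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        idx <- add_atom(toupper(ch), TRUE); i <- i + 1L
      } else {
        stop(sprintf("unsupported SMILES character '%s' in %s", ch, smiles))
      }
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NA_character_
      prev <- idx
    }
  }
  open_rings <- names(ring)[!vapply(ring, is.null, logical(1))]
  if (length(open_rings)) stop("unclosed ring bond(s): ",
                               paste(open_rings, collapse = ", "))
  if (!length(atoms)) stop("empty SMILES")

  atom_df <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), integer(1)),
    h_explicit = vapply(atoms, function(a) as.integer(a$h_explicit), integer(1)),
    stringsAsFactors = FALSE
  )
  bond_df <- if (length(bonds)) data.frame(
    a1 = vapply(bonds, function(b) as.integer(b$a1), integer(1)),
    a2 = vapply(bonds, function(b) as.integer(b$a2), integer(1)),
    order = vapply(bonds, function(b) as.integer(b$order), integer(1)),
    aromatic = vapply(bonds, `[[`, logical(1), "aromatic")
  ) else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                    aromatic = logical(0))
  build_molecule(atom_df, bond_df, smiles)
}

parse_bracket_atom <- function(body, smiles) {
  rest <- sub("^[0-9]+", "", body)                      # isotope label ignored
  m <- regmatches(rest, regexec("^(Cl|Br|[BCNOPSFI]|[bcnops])", rest))[[1L]]
  if (!length(m)) stop("unsupported bracket atom [", body, "] in ", smiles)
  sym <- m[2L]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  rest <- substring(rest, nchar(sym) + 1L)
  rest <- sub("^@{1,2}", "", rest)                      # stereo marks ignored
  h <- 0L
  hm <- regmatches(rest, regexec("^H([0-9]*)", rest))[[1L]]
  if (length(hm)) {
    h <- if (nzchar(hm[2L])) as.integer(hm[2L]) else 1L
    rest <- substring(rest, nchar(hm[1L]) + 1L)
  }
  charge <- 0L
  if (nzchar(rest)) {
    cm <- regmatches(rest, regexec("^([+-])([0-9]+)?([+-]*)$", rest))[[1L]]
    if (!length(cm)) stop("unsupported bracket atom [", body, "] in ", smiles)
    mag <- if (nzchar(cm[3L])) as.integer(cm[3L]) else 1L + nchar(cm[4L])
    charge <- if (cm[2L] == "+") mag else -mag
  }
  list(element = if (aromatic) toupper(sym) else sym,
       aromatic = aromatic, charge = charge, h = h)
}

default_valence <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
                     F = 1L, Cl = 1L, Br = 1L, I = 1L)

build_molecule <- function(atom_df, bond_df, smiles) {
  n <- nrow(atom_df)
  degree <- integer(n)
  bond_sum <- numeric(n)
  for (b in seq_len(nrow(bond_df))) {
    a1 <- bond_df$a1[b]; a2 <- bond_df$a2[b]
    degree[a1] <- degree[a1] + 1L
    degree[a2] <- degree[a2] + 1L
    o <- if (bond_df$aromatic[b]) 1 else bond_df$order[b]
    bond_sum[a1] <- bond_sum[a1] + o
    bond_sum[a2] <- bond_sum[a2] + o
  }
  h_count <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(atom_df$h_explicit[i])) {
      h_count[i] <- atom_df$h_explicit[i]
    } else {
      val <- default_valence[[atom_df$element[i]]]
      if (is.null(val)) val <- 0L
      h_count[i] <- if (atom_df$aromatic[i])
        max(0L, as.integer(val - degree[i] - 1L))
      else
        max(0L, as.integer(val - bond_sum[i]))
    }
  }
  atoms <- data.frame(element = atom_df$element, aromatic = atom_df$aromatic,
                      charge = atom_df$charge, h_count = h_count,
                      degree = degree, stringsAsFactors = FALSE)
  mol <- structure(list(atoms = atoms, bonds = bond_df, smiles = smiles),
                   class = "molecule")
  if (!is_connected(mol)) stop("molecule graph is not connected: ", smiles)
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d heavy atoms, %d bonds  (%s)\n",
              nrow(x$atoms), nrow(x$bonds), x$smiles))
  invisible(x)
}

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  lapply(adj, function(v) if (is.null(v)) integer(0) else sort(v))
}

is_connected <- function(mol) {
  n <- nrow(mol$atoms)
  if (n <= 1L) return(TRUE)
  adj <- adjacency_list(mol)
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  all(seen)
}

#' Permute the atom numbering of a molecule
#'
#' Returns the same molecular graph with atoms relabelled by `perm` (atom `i`
#' becomes atom `perm[i]`). Used to check that fragment keys and holograms do
#' not depend on atom order.
#'
#' @param mol A [parse_smiles()] molecule.
#' @param perm A permutation of `1:n_atoms`.
#' @return A `molecule` with reordered atoms and remapped bonds.
#' @export
permute_molecule <- function(mol, perm) {
  stopifnot(inherits(mol, "molecule"),
            sort(perm) == seq_len(nrow(mol$atoms)))
  inv <- order(perm)
  atoms <- mol$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  new_a1 <- perm[bonds$a1]; new_a2 <- perm[bonds$a2]
  bonds$a1 <- pmin(new_a1, new_a2)
  bonds$a2 <- pmax(new_a1, new_a2)
  structure(list(atoms = atoms, bonds = bonds,
                 smiles = paste0(mol$smiles, " (relabelled)")),
            class = "molecule")
}

#' Read a SMILES file
#'
#' One molecule per line: `SMILES [id] [activity]`, whitespace-separated.
#'
#' @param path File path.
#' @return A data.frame with `id`, `smiles`, `activity` (NA when absent), and
#'   a `molecules` attribute holding the parsed graphs.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  df <- data.frame(
    id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2L) parts[[i]][2L] else as.character(i),
      character(1)),
    smiles = vapply(parts, `[[`, character(1), 1L),
    activity = vapply(parts, function(p)
      if (length(p) >= 3L) as.numeric(p[3L]) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(df, "molecules") <- lapply(df$smiles, parse_smiles)
  df
}

# donor: N/O bearing >= 1 hydrogen; acceptor: N/O without positive charge
donor_acceptor_class <- function(mol) {
  el <- mol$atoms$element
  no <- el %in% c("N", "O")
  donor <- no & mol$atoms$h_count >= 1L
  acceptor <- no & mol$atoms$charge <= 0L
  ifelse(donor & acceptor, "DA",
         ifelse(donor, "D", ifelse(acceptor, "A", "-")))
}
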