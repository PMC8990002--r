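# Glycan composition database: TSV I/O, topology trees in
# nested-parenthesis notation, the canonical N-glycan topology fallback,
# and theoretical B/Y fragment enumeration.

#' Read a glycan composition database
#'
#' Tab-separated with columns `accession`, `composition` (e.g.
#' `"Hex(5)HexNAc(2)"`) and optionally `topology` in nested-parenthesis
#' notation rooted at the peptide, e.g.
#' `pep(HexNAc(HexNAc(Hex(Hex)(Hex))))`.
#'
#' @param path TSV path.
#' @return `data.frame(accession, composition, topology, mass)` sorted
#'   by mass.
#' @export
readGlycanDb <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "composition")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("glycan DB lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"topology" %in% names(tab)) tab$topology <- ""
  tab$topology[is.na(tab$topology)] <- ""
  tab$mass <- vapply(tab$composition,
                     function(x) glycanMass(parseGlycanComposition(x)),
                     numeric(1))
  tab <- tab[order(tab$mass), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' @rdname readGlycanDb
#' @param compositions Character vector of composition strings.
#' @param accessions Optional accession labels.
#' @export
glycanDbFromCompositions <- function(compositions,
                                     accessions = NULL) {
  if (is.null(accessions))
    accessions <- sprintf("G%04d", seq_along(compositions))
  tab <- data.frame(accession = accessions,
                    composition = compositions, topology = "",
                    stringsAsFactors = FALSE)
  tab$mass <- vapply(tab$composition,
                     function(x) glycanMass(parseGlycanComposition(x)),
                     numeric(1))
  tab <- tab[order(tab$mass), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Parse a glycan topology tree
#'
#' Nested-parenthesis notation rooted at the peptide: `pep(...)` wraps
#' the reducing-end monosaccharide; each node is `Name(child)(child)`.
#'
#' @param string Topology string.
#' @return `data.frame(node, name, parent)`; parent 0 is the peptide.
#' @examples
#' parseGlycanTopology("pep(HexNAc(HexNAc(Hex(Hex)(Hex))))")
#' @export
parseGlycanTopology <- function(string) {
  s <- gsub("\\s", "", string)
  pos <- 1L
  nodes <- list()
  readName <- function() {
    m <- regexpr("^[A-Za-z0-9]+", substring(s, pos))
    if (m == -1L) stop("topology parse error at position ", pos,
                       " in ", string, call. = FALSE)
    nm <- regmatches(substring(s, pos), m)
    pos <<- pos + attr(m, "match.length")
    nm
  }
  parseNode <- function(parent) {
    nm <- readName()
    id <- length(nodes) + 1L
    nodes[[id]] <<- data.frame(node = id, name = nm, parent = parent)
    while (pos <= nchar(s) && substring(s, pos, pos) == "(") {
      pos <<- pos + 1L
      parseNode(id)
      if (substring(s, pos, pos) != ")")
        stop("unbalanced parentheses in topology: ", string,
             call. = FALSE)
      pos <<- pos + 1L
    }
    id
  }
  parseNode(0L)
  tree <- do.call(rbind, nodes)
  if (tree$name[1] != "pep")
    stop("topology must be rooted at 'pep': ", string, call. = FALSE)
  # renumber without the pep wrapper; its children become parent-0 nodes
  tree <- tree[-1, , drop = FALSE]
  tree$parent[tree$parent == 1L] <- 0L
  tree$node <- tree$node - 1L
  tree$parent <- ifelse(tree$parent > 0L, tree$parent - 1L, 0L)
  rownames(tree) <- NULL
  tree
}

#' Canonical N-glycan topology for a composition
#'
#' Builds an approximate rooted tree for a composition without explicit
#' structure: chitobiose core (HexNAc-HexNAc), branch mannose with two
#' arm hexoses, core fucose on the reducing-end HexNAc, remaining
#' HexNAc/Hex/NeuAc/NeuGc populated as antennae distributed alternately
#' over the two arms (HexNAc, then Hex, then sialic acid), leftover
#' hexoses as arm chains (oligo-mannose style).  The Y-ion mass set of
#' this fallback matches the true structure for common N-glycans even
#' where branch placement differs.
#'
#' @param comp [GlycanComposition-class] (or coercible), moiety ignored.
#' @return Topology `data.frame(node, name, parent)`.
#' @export
canonicalTopology <- function(comp) {
  comp <- as.glycanComposition(comp)
  cnt <- c(Hex = 0, HexNAc = 0, Fuc = 0, NeuAc = 0, NeuGc = 0)
  extra <- comp@counts[setdiff(names(comp@counts), names(cnt))]
  cnt[names(comp@counts)[names(comp@counts) %in% names(cnt)]] <-
    comp@counts[names(comp@counts) %in% names(cnt)]
  nodes <- data.frame(node = integer(0), name = character(0),
                      parent = integer(0))
  addNode <- function(name, parent) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, name, parent)
    id
  }
  n1 <- if (cnt[["HexNAc"]] >= 1) { cnt[["HexNAc"]] <- cnt[["HexNAc"]] - 1
    addNode("HexNAc", 0L) } else 0L
  n2 <- if (n1 && cnt[["HexNAc"]] >= 1) { cnt[["HexNAc"]] <- cnt[["HexNAc"]] - 1
    addNode("HexNAc", n1) } else 0L
  mb <- if (n2 && cnt[["Hex"]] >= 1) { cnt[["Hex"]] <- cnt[["Hex"]] - 1
    addNode("Hex", n2) } else 0L
  armA <- if (mb && cnt[["Hex"]] >= 1) { cnt[["Hex"]] <- cnt[["Hex"]] - 1
    addNode("Hex", mb) } else 0L
  armB <- if (mb && cnt[["Hex"]] >= 1) { cnt[["Hex"]] <- cnt[["Hex"]] - 1
    addNode("Hex", mb) } else 0L
  # core fucose
  if (cnt[["Fuc"]] >= 1 && n1) { cnt[["Fuc"]] <- cnt[["Fuc"]] - 1
    addNode("Fuc", n1) }
  arms <- c(armA, armB); arms <- arms[arms > 0]
  if (!length(arms)) arms <- max(c(n1, n2, mb, 0L))
  # antennae from remaining HexNAc
  antennae <- integer(0)
  ai <- 1L
  while (cnt[["HexNAc"]] >= 1 && length(arms)) {
    cnt[["HexNAc"]] <- cnt[["HexNAc"]] - 1
    antennae <- c(antennae, addNode("HexNAc", arms[ai]))
    ai <- ai %% length(arms) + 1L
  }
  # one hexose per antenna (galactose), then sialic acids on them
  tips <- integer(0)
  for (a in antennae) {
    if (cnt[["Hex"]] >= 1) { cnt[["Hex"]] <- cnt[["Hex"]] - 1
      tips <- c(tips, addNode("Hex", a)) }
  }
  for (sial in c("NeuAc", "NeuGc")) {
    for (t in tips) {
      if (cnt[[sial]] >= 1) { cnt[[sial]] <- cnt[[sial]] - 1
        addNode(sial, t) }
    }
  }
  # leftover hexoses as arm chains (oligo-mannose)
  chainEnds <- arms
  ci <- 1L
  while (cnt[["Hex"]] >= 1 && length(chainEnds)) {
    cnt[["Hex"]] <- cnt[["Hex"]] - 1
    chainEnds[ci] <- addNode("Hex", chainEnds[ci])
    ci <- ci %% length(chainEnds) + 1L
  }
  # anything left (incl. leftover Fuc/sialic acid, rare residues)
  leftovers <- c(cnt[cnt > 0], extra)
  anchor <- if (length(antennae)) antennae[1] else
    if (length(arms)) arms[1] else n1
  for (nm in names(leftovers)) {
    for (i in seq_len(leftovers[[nm]])) addNode(nm, anchor)
  }
  nodes
}

# Composition (named counts) of a subtree rooted at node id.
.subtreeCounts <- function(tree, id) {
  children <- function(x) tree$node[tree$parent == x]
  todo <- id; keep <- integer(0)
  while (length(todo)) {
    keep <- c(keep, todo[1])
    todo <- c(todo[-1], children(todo[1]))
  }
  table(tree$name[match(keep, tree$node)])
}

#' Theoretical glycan B/Y fragment ions
#'
#' Enumerates single glycosidic-bond cuts of the topology tree: each cut
#' yields a B ion (the detached subtree, oxonium-type, singly charged)
#' and a Y ion (peptide plus the remaining composition) at charges 1 to
#' `maxCharge`.  Duplicate m/z values are merged.
#'
#' @param entry List or db row with `composition` (string or
#'   [GlycanComposition-class]) and optional `topology` (string or
#'   parsed tree).
#' @param pepMass Peptide neutral mass, Da.
#' @param maxCharge Highest Y-ion charge.
#' @return `data.frame(kind, label, mz, charge)`, `kind` in
#'   `{"B", "Y"}`; includes the intact (uncut) Y at each charge.
#' @export
theoreticalGlycanFragments <- function(entry, pepMass, maxCharge = 2L) {
  comp <- as.glycanComposition(entry$composition)
  topo <- entry$topology
  if (is.character(topo)) {
    topo <- if (length(topo) && nzchar(topo[1]))
      parseGlycanTopology(topo[1]) else NULL
  }
  if (is.null(topo)) topo <- canonicalTopology(comp)
  topoCounts <- table(topo$name)
  compCounts <- comp@counts[comp@counts > 0]
  if (!identical(sort(names(topoCounts)), sort(names(compCounts))) ||
      !all(topoCounts[names(compCounts)] == compCounts)) {
    warning("topology inconsistent with composition for ",
            glycanLabel(comp), "; entry skipped")
    return(NULL)
  }
  prot <- massConstants[["proton"]]
  monos <- monosaccharideMasses()
  totalMass <- sum(monos[topo$name])
  rows <- list()
  addY <- function(yMass, label) {
    for (z in seq_len(maxCharge))
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = "Y", label = label, mz = (pepMass + yMass + z * prot) / z,
        charge = z, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(topo))) {
    sub <- .subtreeCounts(topo, topo$node[i])
    bMass <- sum(monos[names(sub)] * as.numeric(sub))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "B", label = paste0("B/", topo$name[i]), mz = bMass + prot,
      charge = 1L, stringsAsFactors = FALSE)
    addY(totalMass - bMass, paste0("Y-", topo$name[i]))
  }
  addY(totalMass, "Y-intact")
  out <- do.call(rbind, rows)
  out <- out[!duplicated(round(out$mz, 4)), , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
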