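#' Construct an ontology graph from term and edge tables
#'
#' An ontology graph is a rooted directed acyclic graph of terms. Edges point
#' from child to parent and carry a relation type (`is_a` or `part_of`); each
#' namespace (e.g. BP, CC, MF) has exactly one root with no parents, and
#' edges never cross namespaces. This constructor validates acyclicity,
#' identifies roots, drops cross-namespace edges, and precomputes the parent
#' and ancestor indices used by feature construction and evaluation.
#'
#' @param terms Data frame with columns `term_id`, `namespace` and optionally
#'   `name`.
#' @param edges Data frame with columns `child`, `parent` and optionally
#'   `relation` (defaults to `is_a`).
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  if (!"name" %in% names(terms)) terms$name <- terms$term_id
  if (!"relation" %in% names(edges) && nrow(edges) > 0) edges$relation <- "is_a"
  if (nrow(edges) == 0) {
    edges <- tibble(child = character(), parent = character(), relation = character())
  }
  terms <- terms |>
    mutate(term_id = as.character(.data$term_id)) |>
    distinct(.data$term_id, .keep_all = TRUE) |>
    arrange(.data$term_id)

  ns_of <- setNames(terms$namespace, terms$term_id)
  bad <- !(edges$child %in% terms$term_id) | !(edges$parent %in% terms$term_id)
  edges <- edges[!bad, , drop = FALSE]
  # cross-namespace edges are dropped, never traversed
  cross <- ns_of[edges$child] != ns_of[edges$parent]
  if (any(cross)) {
    warn(sprintf("Dropped %d cross-namespace edge(s).", sum(cross)))
    edges <- edges[!cross, , drop = FALSE]
  }
  edges <- distinct(edges, .data$child, .data$parent, .keep_all = TRUE)

  parents <- split(edges$parent, factor(edges$child, levels = terms$term_id))
  children <- split(edges$child, factor(edges$parent, levels = terms$term_id))

  # Kahn's algorithm: topological order with parents before children,
  # rejecting cycles by naming a member of one.
  indeg <- lengths(parents)
  queue <- names(indeg)[indeg == 0L]
  topo <- character(0)
  indeg_work <- indeg
  while (length(queue) > 0) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < nrow(terms)) {
    cyc <- setdiff(terms$term_id, topo)
    abort(paste0("Ontology contains a cycle involving term: ", cyc[[1L]]))
  }

  # one parentless root per namespace
  roots <- character(0)
  for (ns in unique(terms$namespace)) {
    ns_terms <- terms$term_id[terms$namespace == ns]
    cand <- ns_terms[lengths(parents[ns_terms]) == 0L]
    if (length(cand) != 1L) {
      abort(sprintf(
        "Namespace %s must have exactly one parentless root, found %d.",
        ns, length(cand)
      ))
    }
    roots[[ns]] <- cand
  }

  # ancestor closure (excluding self) and shortest/longest depth, in
  # topological order so parents are always resolved first
  anc <- setNames(vector("list", nrow(terms)), terms$term_id)
  dep_s <- setNames(rep(NA_integer_, nrow(terms)), terms$term_id)
  dep_l <- dep_s
  for (t in topo) {
    ps <- parents[[t]]
    if (length(ps) == 0L) {
      anc[[t]] <- character(0)
      dep_s[[t]] <- 0L
      dep_l[[t]] <- 0L
    } else {
      anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
      dep_s[[t]] <- min(dep_s[ps]) + 1L
      dep_l[[t]] <- max(dep_l[ps]) + 1L
    }
  }

  structure(
    list(
      terms = terms, edges = edges, roots = roots,
      parents = parents, children = children, topo = topo,
      ancestors = anc, depth_shortest = dep_s, depth_longest = dep_l
    ),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf(
    "<ontology_graph> %d terms, %d edges, root(s): %s\n",
    nrow(x$terms), nrow(x$edges),
    paste(sprintf("%s (%s)", x$roots, names(x$roots)), collapse = ", ")
  ))
  invisible(x)
}

#' @describeIn ontology_graph Term table with namespace, depth and parent count.
#' @param x An `ontology_graph`.
#' @param ... Unused.
#' @export
tidy.ontology_graph <- function(x, ...) {
  x$terms |>
    mutate(
      depth = unname(x$depth_shortest[.data$term_id]),
      n_parents = lengths(x$parents[.data$term_id])
    )
}

#' @describeIn ontology_graph One-row summary.
#' @export
glance.ontology_graph <- function(x, ...) {
  tibble(
    n_terms = nrow(x$terms),
    n_edges = nrow(x$edges),
    n_namespaces = length(x$roots),
    max_depth = max(x$depth_shortest)
  )
}

check_term <- function(graph, term) {
  if (!term %in% graph$terms$term_id) abort(paste0("Unknown term: ", term))
  invisible(term)
}

#' Parse an OBO ontology file
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas. Obsolete terms are dropped; `is_a`
#' edges are always kept; `part_of` relationships are treated as hierarchical
#' edges by default (true-path propagation conventionally traverses them) and
#' can be disabled. Terms left without any path to their namespace root
#' (e.g. a term whose only parent was a disabled `part_of`) are dropped with
#' a warning. Cross-namespace edges are dropped.
#'
#' @param path OBO file path.
#' @param keep_part_of Keep `part_of` relationships as edges (default `TRUE`).
#' @return An `ontology_graph`.
#' @export
parse_obo <- function(path, keep_part_of = TRUE) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0) abort("No stanzas found in OBO file.")

  ids <- character(0); names_ <- character(0); ns <- character(0)
  ech <- character(0); epa <- character(0); erel <- character(0)
  bounds <- c(stanza_starts, length(lines) + 1L)
  for (i in seq_along(stanza_starts)) {
    if (lines[[stanza_starts[[i]]]] != "[Term]") next
    block <- lines[(stanza_starts[[i]] + 1L):(bounds[[i + 1L]] - 1L)]
    get1 <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      if (length(v) == 0) NA_character_ else sub(paste0("^", key, ": "), "", v[[1L]])
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    nm <- get1("name")
    names_ <- c(names_, if (is.na(nm)) id else nm)
    ns <- c(ns, get1("namespace"))
    isa <- block[startsWith(block, "is_a: ")]
    for (v in isa) {
      pa <- stringr::str_trim(sub("!.*$", "", sub("^is_a: ", "", v)))
      ech <- c(ech, id); epa <- c(epa, pa); erel <- c(erel, "is_a")
    }
    if (keep_part_of) {
      po <- block[startsWith(block, "relationship: part_of ")]
      for (v in po) {
        pa <- stringr::str_trim(sub("!.*$", "", sub("^relationship: part_of ", "", v)))
        ech <- c(ech, id); epa <- c(epa, pa); erel <- c(erel, "part_of")
      }
    }
  }
  if (length(ids) == 0) abort("No usable [Term] stanzas in OBO file.")
  if (all(is.na(ns))) ns[] <- "default"
  ns[is.na(ns)] <- "default"

  terms <- tibble(term_id = ids, name = names_, namespace = ns)
  edges <- tibble(child = ech, parent = epa, relation = erel)
  edges <- edges[edges$parent %in% ids & edges$child %in% ids, , drop = FALSE]
  # drop cross-namespace edges before orphan analysis
  ns_of <- setNames(terms$namespace, terms$term_id)
  edges <- edges[ns_of[edges$child] == ns_of[edges$parent], , drop = FALSE]

  # identify the root of each namespace as the parentless term with the
  # largest reachable descendant set; other parentless terms are orphans and
  # are dropped (recursively) with a warning
  repeat {
    has_parent <- unique(edges$child)
    orphans <- character(0)
    for (nsx in unique(terms$namespace)) {
      ns_terms <- terms$term_id[terms$namespace == nsx]
      cand <- setdiff(ns_terms, has_parent)
      if (length(cand) <= 1L) next
      sizes <- vapply(cand, function(r) {
        seen <- r; frontier <- r
        while (length(frontier) > 0) {
          nxt <- setdiff(edges$child[edges$parent %in% frontier], seen)
          seen <- c(seen, nxt); frontier <- nxt
        }
        length(seen)
      }, integer(1))
      keep_root <- cand[which.max(sizes)]
      if (sum(sizes == max(sizes)) > 1L) {
        abort(sprintf("Cannot identify a unique root for namespace %s.", nsx))
      }
      orphans <- c(orphans, setdiff(cand, keep_root))
    }
    if (length(orphans) == 0) break
    warn(sprintf(
      "Dropped %d term(s) with no path to their namespace root: %s",
      length(orphans), paste(head(orphans, 5), collapse = ", ")
    ))
    terms <- terms[!terms$term_id %in% orphans, , drop = FALSE]
    edges <- edges[!edges$child %in% orphans & !edges$parent %in% orphans, , drop = FALSE]
  }

  ontology_graph(terms, edges)
}

#' Query DAG relatives of a term
#'
#' Relations follow the standard reading used by the siblings negative-
#' sampling policy: siblings are children of any parent of the term (minus
#' the term); uncles are siblings of any parent; ancestors and descendants
#' are transitive closures excluding the term itself. All results stay within
#' the term's namespace.
#'
#' @param graph An `ontology_graph`.
#' @param term A term id.
#' @param relation One of `"parents"`, `"children"`, `"siblings"`,
#'   `"uncles"`, `"ancestors"`, `"descendants"`.
#' @return Character vector of term ids (possibly empty), sorted.
#' @export
relatives <- function(graph, term,
                      relation = c("parents", "children", "siblings",
                                   "uncles", "ancestors", "descendants")) {
  check_term(graph, term)
  relation <- match.arg(relation)
  out <- switch(relation,
    parents = graph$parents[[term]],
    children = graph$children[[term]],
    siblings = {
      ps <- graph$parents[[term]]
      setdiff(unique(unlist(graph$children[ps], use.names = FALSE)), term)
    },
    uncles = {
      ps <- graph$parents[[term]]
      gps <- unique(unlist(graph$parents[ps], use.names = FALSE))
      setdiff(unique(unlist(graph$children[gps], use.names = FALSE)), ps)
    },
    ancestors = graph$ancestors[[term]],
    descendants = {
      seen <- character(0); frontier <- term
      while (length(frontier) > 0) {
        nxt <- setdiff(unique(unlist(graph$children[frontier], use.names = FALSE)), seen)
        seen <- c(seen, nxt); frontier <- nxt
      }
      setdiff(seen, term)
    }
  )
  sort(unique(out %||% character(0)))
}

#' Depth of a term in its ontology
#'
#' Depth is the length of the shortest directed path from the term to its
#' namespace root (root depth 0). The longest-path alternative is available
#' via `method = "longest"`.
#'
#' @param graph An `ontology_graph`.
#' @param term A term id (vectorised).
#' @param method `"shortest"` (default) or `"longest"`.
#' @return Integer vector of depths.
#' @export
term_depth <- function(graph, term, method = c("shortest", "longest")) {
  method <- match.arg(method)
  for (t in term) check_term(graph, t)
  d <- if (method == "shortest") graph$depth_shortest else graph$depth_longest
  unname(d[term])
}

#' Write a per-term ontology summary TSV
#'
#' Columns: `term_id`, `namespace`, `depth`, `n_parents`.
#' @param graph An `ontology_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology_summary <- function(graph, path) {
  readr::write_tsv(
    tidy(graph) |> select("term_id", "namespace", "depth", "n_parents"),
    path
  )
  invisible(path)
}
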