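# Low-level unrooted-tree surgery used by the heuristic search: a mutable
# adjacency representation (`utree`) with NNI/SPR/TBR neighbourhood
# generation. Tips are nodes 1..n (labelled); internal nodes unlabelled.

utree_new <- function(labels3) {
  stopifnot(length(labels3) == 3L)
  adj <- list(4L, 4L, 4L, c(1L, 2L, 3L))
  structure(list(adj = adj, labels = c(labels3, NA)), class = "utree")
}

utree_from_phylo <- function(tr) {
  tr <- canonical_tree(tr)
  nn <- max(tr$edge)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(tr$edge))) {
    a <- tr$edge[i, 1]; b <- tr$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  labels <- c(tr$tip.label, rep(NA, nn - length(tr$tip.label)))
  structure(list(adj = adj, labels = labels), class = "utree")
}

utree_to_phylo <- function(ut) {
  # newick via DFS rooted at tip 1's neighbour
  adj <- ut$adj
  start <- adj[[1L]][1]
  nw <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (!length(kids)) return(ut$labels[node])
    paste0("(", paste(vapply(kids, nw, "", parent = node),
                      collapse = ","), ")")
  }
  kids <- setdiff(adj[[start]], 1L)
  txt <- paste0("(", ut$labels[1L], ",",
                paste(vapply(kids, nw, "", parent = start),
                      collapse = ","), ");")
  canonical_tree(ape::read.tree(text = txt))
}

utree_edges <- function(ut) {
  out <- list()
  for (a in seq_along(ut$adj)) {
    for (b in ut$adj[[a]]) if (a < b) out[[length(out) + 1L]] <- c(a, b)
  }
  out
}

ut_disconnect <- function(ut, a, b) {
  ut$adj[[a]] <- setdiff(ut$adj[[a]], b)
  ut$adj[[b]] <- setdiff(ut$adj[[b]], a)
  ut
}

ut_connect <- function(ut, a, b) {
  ut$adj[[a]] <- c(ut$adj[[a]], b)
  ut$adj[[b]] <- c(ut$adj[[b]], a)
  ut
}

# remove a degree-2 node, joining its two neighbours; node stays allocated
# but isolated (reusable as a junction)
ut_dissolve <- function(ut, v) {
  nb <- ut$adj[[v]]
  stopifnot(length(nb) == 2L)
  ut <- ut_disconnect(ut, v, nb[1])
  ut <- ut_disconnect(ut, v, nb[2])
  ut_connect(ut, nb[1], nb[2])
}

# subdivide edge (a,b) with node z
ut_subdivide <- function(ut, a, b, z) {
  ut <- ut_disconnect(ut, a, b)
  ut <- ut_connect(ut, a, z)
  ut_connect(ut, z, b)
}

# attach a new labelled tip in the middle of edge (a,b)
ut_insert_tip <- function(ut, a, b, label) {
  tipid <- length(ut$adj) + 1L
  junc <- tipid + 1L
  ut$adj[[junc]] <- integer(0)
  ut$adj[[tipid]] <- integer(0)
  ut$labels <- c(ut$labels, label, NA)
  ut <- ut_subdivide(ut, a, b, junc)
  ut_connect(ut, tipid, junc)
}

ut_component <- function(ut, start, avoid) {
  seen <- c(start)
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in ut$adj[[v]]) {
      if (w != avoid && !(w %in% seen)) {
        seen <- c(seen, w)
        queue <- c(queue, w)
      }
    }
  }
  seen
}

# All NNI neighbours (2 per internal edge)
ut_nni_neighbours <- function(ut) {
  out <- list()
  for (e in utree_edges(ut)) {
    u <- e[1]; v <- e[2]
    if (length(ut$adj[[u]]) != 3L || length(ut$adj[[v]]) != 3L) next
    us <- setdiff(ut$adj[[u]], v)
    vs <- setdiff(ut$adj[[v]], u)
    for (x in vs) {
      nt <- ut_disconnect(ut, u, us[1])
      nt <- ut_disconnect(nt, v, x)
      nt <- ut_connect(nt, u, x)
      nt <- ut_connect(nt, v, us[1])
      out[[length(out) + 1L]] <- nt
    }
  }
  out
}

# All SPR neighbours: prune the subtree on the v-side of each edge (u,v)
# and regraft on every edge of the remaining component.
ut_spr_neighbours <- function(ut) {
  out <- list()
  for (e in utree_edges(ut)) {
    for (dir in 1:2) {
      u <- e[dir]; v <- e[3 - dir]
      if (length(ut$adj[[u]]) != 3L) next  # need a dissolvable junction
      base <- ut_disconnect(ut, u, v)
      base <- ut_dissolve(base, u)         # u now isolated, reusable
      sub_nodes <- ut_component(base, v, avoid = -1L)
      rest <- setdiff(seq_along(base$adj), c(u, sub_nodes))
      for (f in utree_edges(base)) {
        if (!(f[1] %in% rest) || !(f[2] %in% rest)) next
        nt <- ut_subdivide(base, f[1], f[2], u)
        nt <- ut_connect(nt, u, v)
        out[[length(out) + 1L]] <- nt
      }
    }
  }
  out
}

# All TBR neighbours: like SPR but the pruned part may also be re-entered
# through any of its own edges.
ut_tbr_neighbours <- function(ut) {
  out <- list()
  for (e in utree_edges(ut)) {
    for (dir in 1:2) {
      u <- e[dir]; v <- e[3 - dir]
      if (length(ut$adj[[u]]) != 3L) next
      base <- ut_disconnect(ut, u, v)
      base <- ut_dissolve(base, u)
      sub_nodes <- ut_component(base, v, avoid = -1L)
      rest <- setdiff(seq_along(base$adj), c(u, sub_nodes))
      rest_edges <- Filter(function(f) f[1] %in% rest && f[2] %in% rest,
                           utree_edges(base))
      # candidate re-entry points within the pruned part
      if (length(base$adj[[v]]) == 2L) {
        base2 <- ut_dissolve(base, v)
        sub_edges <- Filter(function(f) f[1] %in% sub_nodes &&
                              f[2] %in% sub_nodes, utree_edges(base2))
        entries <- c(list(NULL), sub_edges)  # NULL = original point v
      } else {
        base2 <- base
        entries <- list(NULL)
      }
      for (entry in entries) {
        for (f in rest_edges) {
          if (is.null(entry)) {
            nt <- ut_subdivide(base, f[1], f[2], u)
            nt <- ut_connect(nt, u, v)
          } else {
            nt <- ut_subdivide(base2, f[1], f[2], u)
            nt <- ut_subdivide(nt, entry[1], entry[2], v)
            nt <- ut_connect(nt, u, v)
          }
          out[[length(out) + 1L]] <- nt
        }
      }
    }
  }
  out
}

# postorder edge matrix (parent, child) of a utree rooted at the
# neighbour of tip node 1
ut_postorder <- function(ut) {
  n <- length(ut$adj)
  root <- ut$adj[[1L]][1]
  parent <- integer(n)
  stack <- root
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    for (w in ut$adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  kids <- rev(pre[-1])
  cbind(parent[kids], kids)
}

ut_neighbours <- function(ut, mode = c("NNI", "SPR", "TBR")) {
  switch(match.arg(mode),
         NNI = ut_nni_neighbours(ut),
         SPR = ut_spr_neighbours(ut),
         TBR = ut_tbr_neighbours(ut))
}
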