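# shifted copy of a matrix: out[i, j] = m[i + dr, j + dc], zero outside
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  sr <- max(1L, 1L - dr):min(nr, nr - dr)
  sc <- max(1L, 1L - dc):min(nc, nc - dc)
  out[sr, sc] <- m[sr + dr, sc + dc]
  out
}

# ordered 8-neighborhood, clockwise from north (P2..P9 of Zhang-Suen)
neighbor_stack <- function(m) {
  list(
    shift_mat(m, -1L,  0L),  # N
    shift_mat(m, -1L,  1L),  # NE
    shift_mat(m,  0L,  1L),  # E
    shift_mat(m,  1L,  1L),  # SE
    shift_mat(m,  1L,  0L),  # S
    shift_mat(m,  1L, -1L),  # SW
    shift_mat(m,  0L, -1L),  # W
    shift_mat(m, -1L, -1L)   # NW
  )
}

#' Skeletonize a binary mask
#'
#' Topology-preserving iterative thinning (Zhang-Suen): two sub-iterations per
#' pass delete border pixels that have 2-6 foreground neighbours, exactly one
#' 0-to-1 transition around the 8-neighbourhood, and the directional
#' conditions of the respective sub-iteration; iteration stops when a full
#' pass deletes nothing. The result is a 1-px-wide medial curve per object,
#' deterministic, and idempotent on curves that are already 1 px wide.
#'
#' @param mask Logical or 0/1 matrix.
#' @return A logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  p <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighbor_stack(p)
      b <- Reduce(`+`, nb)
      # transitions 0 -> 1 in the circular sequence P2 P3 ... P9 P2
      a <- matrix(0L, nrow(p), ncol(p))
      for (k in 1:8) {
        nxt <- nb[[if (k == 8) 1 else k + 1]]
        a <- a + (nb[[k]] == 0L) * (nxt == 1L)
      }
      if (step == 1) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]] == 0L   # P2 P4 P6
        c2 <- nb[[3]] * nb[[5]] * nb[[7]] == 0L   # P4 P6 P8
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]] == 0L   # P2 P4 P8
        c2 <- nb[[1]] * nb[[5]] * nb[[7]] == 0L   # P2 P6 P8
      }
      del <- p == 1L & b >= 2L & b <= 6L & a == 1L & c1 & c2
      if (any(del)) {
        p[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p == 1L
}

# 8-neighbour offsets (clockwise from north)
.off8 <- cbind(
  dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
  dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
)

# m-adjacency degree of each skeleton pixel: orthogonal neighbours always
# count; a diagonal neighbour counts only when neither orthogonal bridge
# pixel is foreground. This removes the spurious triangles of plain
# 8-adjacency on thinned skeletons, so path pixels have degree exactly 2.
m_degree <- function(p) {
  orth <- shift_mat(p, -1L, 0L) + shift_mat(p, 1L, 0L) +
    shift_mat(p, 0L, -1L) + shift_mat(p, 0L, 1L)
  diag_deg <- matrix(0L, nrow(p), ncol(p))
  for (k in c(2L, 4L, 6L, 8L)) {
    dr <- .off8[k, 1L]; dc <- .off8[k, 2L]
    d <- shift_mat(p, dr, dc)
    bridge <- shift_mat(p, dr, 0L) | shift_mat(p, 0L, dc)
    diag_deg <- diag_deg + d * !bridge
  }
  deg <- orth + diag_deg
  deg[p == 0L] <- 0L
  deg
}

# m-adjacent neighbours of one pixel, as a k x 2 matrix
m_nbrs <- function(skel, r, c) {
  nr <- nrow(skel); nc <- ncol(skel)
  out <- matrix(0L, 0L, 2L)
  for (k in 1:8) {
    r2 <- r + .off8[k, 1L]; c2 <- c + .off8[k, 2L]
    if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc || !skel[r2, c2]) next
    if (.off8[k, 1L] != 0L && .off8[k, 2L] != 0L) {
      if (skel[r + .off8[k, 1L], c] || skel[r, c + .off8[k, 2L]]) next
    }
    out <- rbind(out, c(r2, c2))
  }
  out
}

#' Build a skeleton graph
#'
#' Classifies skeleton pixels by their number of skeleton neighbours under
#' m-adjacency (1 = endpoint, >2 = junction; adjacent junction pixels are
#' merged into one node at their centroid), traces the pixel paths between
#' nodes, consolidates junction clutter (junction pairs connected by very
#' short paths, tiny loops), and prunes spur branches
#' (endpoint-to-junction paths) shorter than `prune_px`. Junction nodes left
#' with two incident edges are spliced out so that a filament crossing debris
#' does not fragment.
#'
#' @param skeleton Logical matrix from [skeletonize()] (1-px-wide).
#' @param prune_px Spur branches shorter than this many pixels are removed
#'   (default 8 px, about 2.5 um at the default calibration: long enough to
#'   remove thinning whiskers, short enough to keep true branches).
#' @return An object of class `skeleton_graph`: list with `nodes` (tibble:
#'   `id`, `kind` in endpoint/junction/cycle, `row`, `col`) and `edges` (list
#'   of lists with `id`, `node_a`, `node_b`, `path` n x 2 matrix of
#'   (row, col)).
#' @export
build_graph <- function(skeleton, prune_px = 8) {
  skel <- skeleton > 0
  for (pass in 1:5) {
    g <- raw_graph(skel)
    if (length(g$edges) == 0L || prune_px <= 0) break
    spur <- vapply(g$edges, function(e) {
      ka <- g$nodes$kind[e$node_a]; kb <- g$nodes$kind[e$node_b]
      nrow(e$path) < prune_px &&
        ((ka == "endpoint" && kb == "junction") ||
         (kb == "endpoint" && ka == "junction"))
    }, logical(1))
    if (!any(spur)) break
    # remove spur path pixels except those inside junction clusters
    junk <- g$junction_map
    for (e in g$edges[spur]) {
      for (i in seq_len(nrow(e$path))) {
        rc <- e$path[i, ]
        if (junk[rc[1L], rc[2L]] == 0L) skel[rc[1L], rc[2L]] <- FALSE
      }
    }
  }
  g <- contract_junctions(g)
  g <- splice_degree2(g)
  # junction consolidation can expose new short spurs: drop them graph-level
  repeat {
    spur <- vapply(g$edges, function(e) {
      ka <- g$nodes$kind[e$node_a]; kb <- g$nodes$kind[e$node_b]
      nrow(e$path) < prune_px &&
        ((ka == "endpoint" && kb == "junction") ||
         (kb == "endpoint" && ka == "junction"))
    }, logical(1))
    if (!any(spur)) break
    g$edges <- unname(g$edges[!spur])
    g <- splice_degree2(g)
  }
  for (i in seq_along(g$edges)) g$edges[[i]]$id <- i
  structure(g[c("nodes", "edges")], class = "skeleton_graph", skeleton = skel)
}

# graph construction without pruning, under m-adjacency
raw_graph <- function(skel) {
  p <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  deg <- m_degree(p)
  endpoint <- skel & deg <= 1L          # includes isolated pixels
  junction <- skel & deg >= 3L
  # junction clusters: 8-connected groups of junction pixels, one node each
  jl <- from_ebimage(EBImage::bwlabel(as_ebimage(junction * 1)))
  storage.mode(jl) <- "integer"
  n_j <- max(jl, 0L)
  node_rows <- list()
  node_map <- matrix(0L, nrow(skel), ncol(skel))
  nid <- 0L
  if (n_j > 0L) {
    idx <- which(jl > 0L, arr.ind = TRUE)
    for (j in seq_len(n_j)) {
      px <- idx[jl[idx] == j, , drop = FALSE]
      nid <- nid + 1L
      node_rows[[nid]] <- list(id = nid, kind = "junction",
                               row = mean(px[, 1L]), col = mean(px[, 2L]))
      node_map[px] <- nid
    }
  }
  ep <- which(endpoint, arr.ind = TRUE)
  for (i in seq_len(nrow(ep))) {
    nid <- nid + 1L
    node_rows[[nid]] <- list(id = nid, kind = "endpoint",
                             row = ep[i, 1L], col = ep[i, 2L])
    node_map[ep[i, 1L], ep[i, 2L]] <- nid
  }
  edges <- list()
  eid <- 0L
  visited <- matrix(FALSE, nrow(skel), ncol(skel))
  seen_pairs <- character()
  node_px <- which(node_map > 0L, arr.ind = TRUE)
  nc <- ncol(skel)
  add_node <- function(kind, r, c) {
    nid <<- nid + 1L
    node_rows[[nid]] <<- list(id = nid, kind = kind, row = r, col = c)
    node_map[r, c] <<- nid
    nid
  }
  for (i in seq_len(nrow(node_px))) {
    r0 <- node_px[i, 1L]; c0 <- node_px[i, 2L]
    id0 <- node_map[r0, c0]
    nbs <- m_nbrs(skel, r0, c0)
    for (k in seq_len(nrow(nbs))) {
      r <- nbs[k, 1L]; cc <- nbs[k, 2L]
      idn <- node_map[r, cc]
      if (idn > 0L) {
        if (idn == id0) next  # same junction cluster
        key <- paste(sort(c(r0 * nc + c0, r * nc + cc)), collapse = "-")
        if (key %in% seen_pairs) next
        seen_pairs <- c(seen_pairs, key)
        eid <- eid + 1L
        edges[[eid]] <- list(id = eid, node_a = id0, node_b = idn,
                             path = rbind(c(r0, c0), c(r, cc)))
        next
      }
      if (visited[r, cc]) next
      # walk along degree-2 pixels until the next node pixel
      path <- list(c(r0, c0), c(r, cc))
      visited[r, cc] <- TRUE
      pr <- r0; pc <- c0; cr <- r; ccol <- cc
      end_id <- 0L
      repeat {
        nxt <- NULL
        cand <- m_nbrs(skel, cr, ccol)
        for (m in seq_len(nrow(cand))) {
          r2 <- cand[m, 1L]; c2 <- cand[m, 2L]
          if (r2 == pr && c2 == pc) next
          if (node_map[r2, c2] > 0L) { nxt <- c(r2, c2); break }
          if (!visited[r2, c2] && is.null(nxt)) nxt <- c(r2, c2)
        }
        if (is.null(nxt)) break
        path[[length(path) + 1L]] <- nxt
        if (node_map[nxt[1L], nxt[2L]] > 0L) {
          end_id <- node_map[nxt[1L], nxt[2L]]
          break
        }
        visited[nxt[1L], nxt[2L]] <- TRUE
        pr <- cr; pc <- ccol; cr <- nxt[1L]; ccol <- nxt[2L]
      }
      if (end_id == 0L) {
        # dead-ended walk (visited pixels ahead): close it with a new node
        last <- path[[length(path)]]
        end_id <- add_node("endpoint", last[1L], last[2L])
      }
      eid <- eid + 1L
      edges[[eid]] <- list(id = eid, node_a = id0, node_b = end_id,
                           path = do.call(rbind, path))
    }
  }
  # closed loops with no endpoint/junction: remaining unvisited degree-2 px
  deg2 <- skel & deg == 2L
  leftover <- deg2 & !visited & node_map == 0L
  while (any(leftover)) {
    start <- which(leftover, arr.ind = TRUE)[1L, , drop = TRUE]
    cyc_id <- add_node("cycle", start[1L], start[2L])
    path <- list(c(start[1L], start[2L]))
    visited[start[1L], start[2L]] <- TRUE
    pr <- -1L; pc <- -1L; cr <- start[1L]; ccol <- start[2L]
    repeat {
      nxt <- NULL
      cand <- m_nbrs(skel, cr, ccol)
      for (m in seq_len(nrow(cand))) {
        r2 <- cand[m, 1L]; c2 <- cand[m, 2L]
        if ((r2 == pr && c2 == pc) || visited[r2, c2]) next
        nxt <- c(r2, c2); break
      }
      if (is.null(nxt)) break
      path[[length(path) + 1L]] <- nxt
      visited[nxt[1L], nxt[2L]] <- TRUE
      pr <- cr; pc <- ccol; cr <- nxt[1L]; ccol <- nxt[2L]
    }
    path[[length(path) + 1L]] <- c(start[1L], start[2L])
    eid <- eid + 1L
    edges[[eid]] <- list(id = eid, node_a = cyc_id, node_b = cyc_id,
                         path = do.call(rbind, path))
    leftover <- deg2 & !visited & node_map == 0L
  }
  nodes <- if (nid == 0L) {
    tibble(id = integer(), kind = character(), row = numeric(), col = numeric())
  } else {
    tibble(
      id = vapply(node_rows, `[[`, integer(1), "id"),
      kind = vapply(node_rows, `[[`, character(1), "kind"),
      row = vapply(node_rows, function(x) as.numeric(x$row), numeric(1)),
      col = vapply(node_rows, function(x) as.numeric(x$col), numeric(1))
    )
  }
  list(nodes = nodes, edges = edges, junction_map = node_map * (jl > 0L))
}

graph_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  for (e in g$edges) {
    deg[e$node_a] <- deg[e$node_a] + 1L
    deg[e$node_b] <- deg[e$node_b] + 1L
  }
  deg
}

# consolidate junction clutter: thinning blunt caps and crossings produces
# pairs of junction nodes a few pixels apart (often as tiny 2-cycles); merge
# junction nodes connected by very short paths and drop tiny self-loops
contract_junctions <- function(g, merge_px = 6L) {
  repeat {
    drop <- vapply(g$edges, function(e)
      e$node_a == e$node_b && nrow(e$path) <= merge_px + 2L, logical(1))
    if (any(drop)) {
      g$edges <- g$edges[!drop]
      next
    }
    short_jj <- which(vapply(g$edges, function(e) {
      e$node_a != e$node_b && nrow(e$path) <= merge_px &&
        g$nodes$kind[e$node_a] == "junction" &&
        g$nodes$kind[e$node_b] == "junction"
    }, logical(1)))
    if (length(short_jj) == 0L) break
    e <- g$edges[[short_jj[1L]]]
    keep <- e$node_a; gone <- e$node_b
    g$nodes$row[keep] <- (g$nodes$row[keep] + g$nodes$row[gone]) / 2
    g$nodes$col[keep] <- (g$nodes$col[keep] + g$nodes$col[gone]) / 2
    g$nodes$kind[gone] <- "merged"
    g$edges[[short_jj[1L]]] <- NULL
    g$edges <- lapply(g$edges, function(ed) {
      if (ed$node_a == gone) ed$node_a <- keep
      if (ed$node_b == gone) ed$node_b <- keep
      ed
    })
  }
  g$edges <- unname(g$edges)
  g
}

# splice out junction nodes of degree 2 (artifacts of spur pruning)
splice_degree2 <- function(g) {
  repeat {
    deg <- graph_degrees(g)
    cand <- which(g$nodes$kind == "junction" & deg == 2L)
    if (length(cand) == 0L) break
    nid <- cand[1L]
    inc <- which(vapply(g$edges, function(e)
      e$node_a == nid || e$node_b == nid, logical(1)))
    if (length(inc) == 1L) {
      # both ends at the same node: becomes a cycle-like edge, leave it
      g$nodes$kind[nid] <- "cycle"
      next
    }
    e1 <- g$edges[[inc[1L]]]; e2 <- g$edges[[inc[2L]]]
    p1 <- if (e1$node_b == nid) e1$path else e1$path[rev(seq_len(nrow(e1$path))), , drop = FALSE]
    a1 <- if (e1$node_b == nid) e1$node_a else e1$node_b
    p2 <- if (e2$node_a == nid) e2$path else e2$path[rev(seq_len(nrow(e2$path))), , drop = FALSE]
    b2 <- if (e2$node_a == nid) e2$node_b else e2$node_a
    merged <- list(id = e1$id, node_a = a1, node_b = b2,
                   path = rbind(p1, p2[-1L, , drop = FALSE]))
    g$edges[[inc[1L]]] <- merged
    g$edges[[inc[2L]]] <- NULL
    g$nodes$kind[nid] <- "spliced"
  }
  g$edges <- unname(g$edges)
  for (i in seq_along(g$edges)) g$edges[[i]]$id <- i
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$kind == "endpoint"), " endpoints, ",
      sum(x$nodes$kind == "junction"), " junctions), ",
      length(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Split a skeleton graph into ordered point paths
#'
#' Emits one ordered pixel path per graph edge, from `node_a` to `node_b`;
#' branches meeting at a junction share the junction pixels but are separate
#' paths, ready for spline parameterization and later recombination.
#'
#' @param graph A `skeleton_graph`.
#' @return A list of n x 2 matrices of (row, col) pixel coordinates; each
#'   carries an attribute `end_kinds` with the node kinds at its two ends.
#' @export
split_at_junctions <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  lapply(graph$edges, function(e) {
    p <- e$path
    colnames(p) <- c("row", "col")
    attr(p, "end_kinds") <- c(graph$nodes$kind[e$node_a],
                              graph$nodes$kind[e$node_b])
    p
  })
}
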