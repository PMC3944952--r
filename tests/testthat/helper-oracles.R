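# Independent oracles and shared fixtures for the test suite.

# naive depth-first reachability over a structural edge table, recomputed
# from scratch per start node; deliberately independent of the package's
# breadth-first implementation
dfs_reach <- function(edges, start, direction = c("up", "down")) {
  direction <- match.arg(direction)
  from <- if (direction == "up") edges$subject else edges$object
  to <- if (direction == "up") edges$object else edges$subject
  visited <- character(0L)
  stack <- start
  while (length(stack)) {
    node <- stack[[1L]]
    stack <- stack[-1L]
    for (nb in to[from == node]) {
      if (nb != start && !nb %in% visited) {
        visited <- c(visited, nb)
        stack <- c(nb, stack)
      }
    }
  }
  visited
}

# part_of-family edge subset of an ontology, as used by the closure oracle
part_family_edges <- function(ont) {
  st <- ont$structural
  st[st$relation %in% c("part_of", "regional_part_of"), , drop = FALSE]
}

# the worked-example ontology is immutable; build it once per test run
fixture_ont <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_fixture_ontology()
    cache
  }
})

# preferred names for a vector of ids
nm <- function(ont, ids) {
  unname(vapply(ids, function(i) class_name(ont, i), character(1L)))
}

# full Talairach label for the superior-frontal worked example
TAL_BA6 <- "Right Cerebrum.Frontal Lobe.Superior Frontal Gyrus.Gray Matter.Brodmann area 6"
TAL_BA20 <- "Right Cerebrum.Temporal Lobe.Inferior Temporal Gyrus.Gray Matter.Brodmann area 20"
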