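# Shared test helpers: independent brute-force oracles and tiny generators.

# random labelled descriptor matrix (independent of the package generators)
rand_labelled_matrix <- function(n, p, seed) {
  withr::with_seed(seed, {
    v <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("mol%02d", seq_len(n)),
                                sprintf("d%02d", seq_len(p))))
    labels <- sample(c("permeant", "non_permeant"), n, replace = TRUE)
    # ensure both classes present
    labels[1] <- "permeant"; labels[2] <- "non_permeant"
    descriptor_matrix(v, labels = labels)
  })
}

# naive majority vote with the package's declared tie rules, written
# independently: counts via explicit loop
oracle_vote <- function(labs) {
  uniq <- sort(unique(labs))
  counts <- vapply(uniq, function(u) sum(labs == u), integer(1))
  best <- uniq[counts == max(counts)]
  if (length(best) > 1 && "non_permeant" %in% best) return("non_permeant")
  best[1]
}

# brute-force leave-one-out KNN: explicit loops and manual selection sort,
# no dist(), no order() on the full vector
oracle_loo <- function(dm, subset, k) {
  X <- dm$values[, subset, drop = FALSE]
  lab <- dm$labels
  n <- nrow(X)
  correct <- 0L
  pred <- character(n)
  for (i in seq_len(n)) {
    d <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      if (j == i) next
      d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
    # pick k nearest, ties to the lower index
    pool <- setdiff(seq_len(n), i)
    chosen <- integer(0)
    for (step in seq_len(k)) {
      best <- pool[1]
      for (j in pool) if (d[j] < d[best]) best <- j  # strict: keeps lowest index on ties
      chosen <- c(chosen, best)
      pool <- setdiff(pool, best)
    }
    pred[i] <- oracle_vote(lab[chosen])
    if (pred[i] == lab[i]) correct <- correct + 1L
  }
  list(n_correct = correct, pred = pred)
}

# hand-written minimal PDB file; returns its path
write_toy_pdb <- function(lines_spec, path = tempfile(fileext = ".pdb")) {
  # lines_spec: data.frame(record, name, resid, chain, resno, x, y, z, element)
  fmt <- function(r)
    sprintf("%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r$record, r$serial, r$name, r$resid, r$chain, r$resno,
            r$x, r$y, r$z, 1.00, 0.00, r$element)
  lines_spec$serial <- seq_len(nrow(lines_spec))
  writeLines(c(vapply(seq_len(nrow(lines_spec)),
                      function(i) fmt(lines_spec[i, ]), character(1)),
               "END"), path)
  path
}

toy_mixed_pdb <- function() {
  write_toy_pdb(data.frame(
    record = c("ATOM", "ATOM", "ATOM", "HETATM", "HETATM"),
    name = c("CA", "N", "O", "C1", "O"),
    resid = c("ALA", "ALA", "ALA", "LIG", "HOH"),
    chain = "A", resno = 1:5,
    x = c(0, 1, 0, 2, 3), y = c(0, 0, 1, 2, 3), z = c(0, 0, 0, 2, 3),
    element = c("C", "N", "O", "C", "O"),
    stringsAsFactors = FALSE))
}
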