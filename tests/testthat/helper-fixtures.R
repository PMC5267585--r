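# shared fixtures and independent oracles used across test files

PARAMS <- load_species_params()
SOIL <- soil_params()
CURVES <- run_all_spinups(PARAMS, SOIL, years = 300)

uniform_landscape <- function(class = "MapleGum", n = 10, stratum = "Wet",
                              age = 40L) {
  new_landscape(rep(class, n * n), stratum, age, n, n)
}

mature_landscape <- function(class = "MapleGum", n = 10, stratum = "Wet",
                             age = 40L) {
  init_stocks(uniform_landscape(class, n, stratum, age), PARAMS)
}

# closed-form discrete single-pool solution B(t) = (I/m)(1 - (1 - m)^t)
single_pool_curve <- function(inflow, m, t) (inflow / m) * (1 - (1 - m)^t)

# brute-force 8-neighbour proportion, independent of the moving-window code
adjacency_oracle <- function(state_mat, target) {
  nr <- nrow(state_mat); nc <- ncol(state_mat)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    hits <- 0L; valid <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
      valid <- valid + 1L
      if (!is.na(state_mat[rr, c2]) && state_mat[rr, c2] == target)
        hits <- hits + 1L
    }
    out[r, cc] <- hits / valid
  }
  out
}

# flood-fill 8-connectivity check (self-contained oracle)
is_connected8 <- function(cells, n_rows, n_cols) {
  if (!length(cells)) return(TRUE)
  nb8 <- function(x) {
    r <- (x - 1L) %/% n_cols; cc <- (x - 1L) %% n_cols
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      ok <- rr >= 0 & rr < n_rows & c2 >= 0 & c2 < n_cols
      out <- c(out, rr[ok] * n_cols + c2[ok] + 1L)
    }
    unique(out)
  }
  inmask <- rep(FALSE, n_rows * n_cols)
  inmask[cells] <- TRUE
  seen <- rep(FALSE, n_rows * n_cols)
  queue <- cells[1]; seen[cells[1]] <- TRUE
  while (length(queue)) {
    nb <- nb8(queue)
    nb <- nb[inmask[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- nb
  }
  sum(seen) == length(cells)
}
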