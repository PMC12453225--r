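# shared helpers: small grids and oracles used across test files

# grid with k corrected founder cells in a compact block near the centre
markedGrid <- function(side, k = 1, boundaryMode = "periodic") {
    g <- BasalGrid(side, side, boundaryMode)
    cx <- floor(side / 2)
    placed <- 0L
    for (r in 0:side) {
        for (dx in -r:r) for (dy in -r:r) {
            if (max(abs(dx), abs(dy)) != r || placed >= k) next
            i <- cx + dx + 1L; j <- cx + dy + 1L
            if (i < 1L || i > side || j < 1L || j > side) next
            if (g@corrected[i, j] == 0L) {
                placed <- placed + 1L
                g@corrected[i, j] <- 1L
                g@cloneId[i, j] <- placed
            }
        }
        if (placed >= k) break
    }
    stopifnot(placed == k)
    g@nextCloneId <- placed + 1L
    g
}

# independent 4-connectivity check (BFS over a set of 1-based site
# indices on a side x side non-periodic lattice)
isConnected4 <- function(sites, side) {
    if (length(sites) <= 1) return(TRUE)
    inset <- logical(side * side)
    inset[sites] <- TRUE
    seen <- logical(side * side)
    queue <- sites[1]
    seen[sites[1]] <- TRUE
    found <- 1L
    while (length(queue)) {
        s <- queue[1]; queue <- queue[-1]
        x <- (s - 1L) %% side; y <- (s - 1L) %/% side
        for (d in 1:4) {
            xx <- x + c(-1L, 1L, 0L, 0L)[d]
            yy <- y + c(0L, 0L, -1L, 1L)[d]
            if (xx < 0 || xx >= side || yy < 0 || yy >= side) next
            t <- xx + yy * side + 1L
            if (inset[t] && !seen[t]) {
                seen[t] <- TRUE; found <- found + 1L
                queue <- c(queue, t)
            }
        }
    }
    found == length(sites)
}
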