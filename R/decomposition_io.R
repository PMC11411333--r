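# Plain-text persistence of decompositions: A.tsv, P.tsv and a JSON sidecar
# carrying the rank, seed, per-pattern restart stability and the per-gene
# row scaling (needed to project new data consistently).

#' Write a decomposition to a directory
#'
#' @param decomp A `pattern_decomposition`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_decomposition <- function(decomp, dir) {
  stopifnot(inherits(decomp, "pattern_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_full(data.frame(gene_id = rownames(decomp$A), decomp$A,
                            check.names = FALSE),
                 file.path(dir, "A.tsv"))
  write_tsv_full(data.frame(pattern = rownames(decomp$P), decomp$P,
                            check.names = FALSE),
                 file.path(dir, "P.tsv"))
  jsonlite::write_json(list(K = decomp$K, seed = decomp$seed,
                            converged = decomp$converged,
                            final_objective = utils::tail(decomp$objective_trace, 1),
                            restart_stability = as.numeric(decomp$restart_stability),
                            row_scaling = as.list(decomp$row_scaling)),
                       file.path(dir, "decomposition.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a decomposition written by [write_decomposition()]
#'
#' @param dir Directory containing `A.tsv`, `P.tsv`, `decomposition.json`.
#' @return A `pattern_decomposition`.
#' @export
read_decomposition <- function(dir) {
  atab <- utils::read.delim(file.path(dir, "A.tsv"), check.names = FALSE)
  A <- as.matrix(atab[, -1L, drop = FALSE])
  rownames(A) <- as.character(atab[[1L]])
  ptab <- utils::read.delim(file.path(dir, "P.tsv"), check.names = FALSE)
  P <- as.matrix(ptab[, -1L, drop = FALSE])
  rownames(P) <- as.character(ptab[[1L]])
  js <- jsonlite::read_json(file.path(dir, "decomposition.json"),
                            simplifyVector = TRUE)
  structure(list(A = A, P = P, K = js$K,
                 objective_trace = js$final_objective,
                 restart_stability = as.numeric(js$restart_stability),
                 row_scaling = unlist(js$row_scaling),
                 converged = js$converged, seed = js$seed),
            class = "pattern_decomposition")
}
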