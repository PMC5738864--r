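# small in-code fixtures shared across test files

toyExpression <- function(values, nNaive = 2, nPlastic = 2,
                          scale = "raw") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- c(sprintf("n%d", seq_len(nNaive)),
                        sprintf("p%d", seq_len(nPlastic)))
  PlasticExpression(values,
                    groups = rep(c("naive", "plastic"),
                                 c(nNaive, nPlastic)),
                    scale = scale)
}

# network from a bare edge list given as a 2-column character matrix
toyNetwork <- function(..., method = "glasso") {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  makeGeneNetwork(data.frame(from = e[, 1], to = e[, 2],
                             weight = 1, stringsAsFactors = FALSE),
                  method = method)
}

extfile <- function(name) system.file("extdata", name,
                                      package = "plasticnet")
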