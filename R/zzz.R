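#' @useDynLib dganet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd qt dist pnorm dnorm mvfft fft
#' @importFrom utils write.csv modifyList
#' @importFrom grDevices chull
"_PACKAGE"
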