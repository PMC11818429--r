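# Independently coded brute-force oracle for the multi-label metrics:
# explicit per-sample set arithmetic via which()/intersect()/union(),
# deliberately sharing no code with the package implementation.
oracle_multilabel <- function(truth, pred) {
  n <- nrow(truth); M <- ncol(truth)
  pr <- cv <- ac <- at <- af <- numeric(n)
  for (i in seq_len(n)) {
    Y <- which(truth[i, ] == 1L)
    Ystar <- which(pred[i, ] == 1L)
    I <- length(intersect(Y, Ystar))
    U <- length(union(Y, Ystar))
    pr[i] <- if (length(Ystar) == 0L) as.numeric(length(Y) == 0L)
             else I / length(Ystar)
    cv[i] <- if (length(Y) == 0L) as.numeric(length(Ystar) == 0L)
             else I / length(Y)
    ac[i] <- if (U == 0L) 1 else I / U
    at[i] <- as.numeric(setequal(Y, Ystar))
    af[i] <- (U - I) / M
  }
  c(precision = mean(pr), coverage = mean(cv), accuracy = mean(ac),
    absolute_true = mean(at), absolute_false = mean(af))
}
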