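# Shared fixtures, all built in code at test time.

# two well-separated 2-D Gaussian blobs (linearly separable toy problem)
makeBlobs <- function(nPerClass = 10, sep = 4, seed = 1) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(2 * nPerClass, mean = -sep / 2), ncol = 2),
               matrix(rnorm(2 * nPerClass, mean = sep / 2), ncol = 2))
    list(X = X,
         y = rep(c("interictal", "ictal"), each = nPerClass))
}

# a tiny hand-specified AE model for arithmetic checks
tinyModel <- function(W_E, b_E, W_D, b_D) {
    n <- nrow(W_E); m <- ncol(W_E)
    new("AEModel", W_E = W_E, b_E = b_E, W_D = W_D, b_D = b_D,
        n = as.integer(n), m = as.integer(m),
        encoderActivation = "satlin", decoderActivation = "purelin")
}

.edfPad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

# write a minimal 16-bit EDF file: `signals` is a list of equal-length
# numeric vectors (physical units), one data record per second
writeTinyEDF <- function(path, signals, fs = 256,
                         labels = paste0("CH", seq_along(signals)),
                         physMin = -100, physMax = 100,
                         sprOverride = NULL) {
    ns <- length(signals)
    len <- length(signals[[1]])
    nRec <- len %/% fs
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- paste0(.edfPad("0", 8), .edfPad("test patient", 80),
                  .edfPad("test recording", 80), .edfPad("01.01.20", 8),
                  .edfPad("00.00.00", 8), .edfPad(256 * (ns + 1), 8),
                  .edfPad("", 44), .edfPad(nRec, 8), .edfPad(1, 8),
                  .edfPad(ns, 4))
    writeChar(hdr, con, eos = NULL)
    spr <- if (is.null(sprOverride)) rep(fs, ns) else sprOverride
    fields <- c(vapply(labels, .edfPad, "", width = 16),
                vapply(rep("", ns), .edfPad, "", width = 80),
                vapply(rep("uV", ns), .edfPad, "", width = 8),
                vapply(rep(physMin, ns), .edfPad, "", width = 8),
                vapply(rep(physMax, ns), .edfPad, "", width = 8),
                vapply(rep(-32768, ns), .edfPad, "", width = 8),
                vapply(rep(32767, ns), .edfPad, "", width = 8),
                vapply(rep("", ns), .edfPad, "", width = 80),
                vapply(spr, .edfPad, "", width = 8),
                vapply(rep("", ns), .edfPad, "", width = 32))
    writeChar(paste(fields, collapse = ""), con, eos = NULL)
    gain <- 65535 / (physMax - physMin)
    for (r in seq_len(nRec)) {
        for (s in seq_len(ns)) {
            seg <- signals[[s]][((r - 1) * fs + 1):(r * fs)]
            dig <- as.integer(round((seg - physMin) * gain) - 32768)
            writeBin(dig, con, size = 2L, endian = "little")
        }
    }
    invisible(path)
}
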