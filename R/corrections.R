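# Pluggable registry of batch-correction methods. Each method is a function
# (table, ...) -> CorrectionResult; external corrections (e.g. a table
# corrected by an outside tool such as NormAE) can be registered so their
# output flows through the same evaluation machinery.
.correction_registry <- new.env(parent = emptyenv())

#' Register or list batch-correction methods
#'
#' `registerCorrectionMethod` installs a correction function under a name;
#' `correctionMethods` lists the registered names. Built-ins: `"combat"`,
#' `"waveica"` and the pass-through `"none"`.
#'
#' @param name method name (used in method specs and grid labels)
#' @param fun function `(table, ...) -> CorrectionResult`
#' @param label display label; default `name`
#' @return `correctionMethods()` returns a character vector of names.
#' @export
registerCorrectionMethod <- function(name, fun, label = name) {
    stopifnot(is.character(name), is.function(fun))
    assign(name, list(fun = fun, label = label),
           envir = .correction_registry)
    invisible(name)
}

#' @rdname registerCorrectionMethod
#' @export
correctionMethods <- function() sort(ls(.correction_registry))

.initRegistry <- function() {
    registerCorrectionMethod("none", function(table, ...) {
        new("CorrectionResult", table = table, model = NULL,
            method = "none", label = "raw", parameters = list(),
            log = character())
    }, label = "raw")
    registerCorrectionMethod("combat", combatCorrect, label = "Combat")
    registerCorrectionMethod("waveica", waveicaCorrect, label = "WaveICA")
}

.methodLabel <- function(pre, method) {
    base <- switch(method, none = NULL, combat = "Combat",
                   waveica = "WaveICA", method)
    if (identical(pre, "tic")) {
        if (is.null(base)) "TIC" else paste("TIC +", base)
    } else {
        if (is.null(base)) "raw" else base
    }
}

#' Run a grid of corrections over raw and TIC-normalized input
#'
#' Applies each configured (input-normalization, method) cell to the full
#' table - QCS and tissue observations corrected together in one matrix,
#' unsupervised - and labels the results the way a method-comparison table
#' reads them: `raw`, `TIC`, `TIC + Combat`, `TIC + WaveICA`, `Combat`,
#' `WaveICA`.
#'
#' @param table a \linkS4class{FeatureTable} (raw scale)
#' @param method_specs list of `list(pre = "raw"|"tic", method = <name>,
#'   args = <list>)`; default: the six-cell grid above
#' @param batch_key batch metadata column passed to the methods
#' @return named list of \linkS4class{CorrectionResult}, names = labels
#' @export
applyCorrections <- function(table, method_specs = NULL, batch_key = "day") {
    if (is.null(method_specs))
        method_specs <- defaultPipelineConfig()$methods
    out <- list()
    for (spec in method_specs) {
        pre <- if (is.null(spec$pre)) "raw" else spec$pre
        method <- spec$method
        if (!method %in% correctionMethods())
            stop("unknown correction method '", method,
                 "'; registered methods: ",
                 paste(correctionMethods(), collapse = ", "))
        input <- switch(pre,
                        raw = table,
                        tic = ticNormalize(table),
                        stop("unknown pre-normalization '", pre, "'"))
        entry <- get(method, envir = .correction_registry)
        args <- c(list(input), spec$args)
        if (method %in% c("combat", "waveica") && is.null(args$batch_key))
            args$batch_key <- batch_key
        res <- do.call(entry$fun, args)
        res@label <- .methodLabel(pre, method)
        out[[res@label]] <- res
    }
    out
}
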