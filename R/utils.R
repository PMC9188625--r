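# Resolve the design/outcome pair from a ModelFrame or a plain list with
# elements X and Y (useful for resampling mechanics on raw matrices).
.getXY <- function(frame) {
    if (is(frame, "ModelFrame")) return(list(X = frame@X, Y = frame@Y))
    if (is.list(frame) && !is.null(frame$X) && !is.null(frame$Y))
        return(list(X = as.matrix(frame$X), Y = as.matrix(frame$Y)))
    stop("expected a ModelFrame or a list with elements X and Y")
}
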