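>OmpR_syn
MLKRWYKQWQFYVYWIMWGWNQCFKWWIFDWCGLESEEPNANFNERIELGDNPDQCDTIFGGQSGGAEMKCRTSYNIKDWCIQKLNISTFASRTCWWWYTLVMEITDAYVMVVRS
>RstA_syn
MLKRWYKQWQFYVYWRMWGWNFCMNWMPFWWAGLAIEEFNANFHACIELGNLPDQCDTGEGEQSGGAEMKMRTSYNCKDWKQQNLSISVFAKTTCWWWMWNVMEIADATAPVVTS
>CpxR_syn
TKRMLKRLYKAWQFYEKWIMWGPRNIFKSWCFDWCGGESEEPNANFPERIEEGDNPDHCDTIFGGISGLAEMTCRFAYNIKDRCIQALNISNVFSRECWWWYTLVMEYTFAYVMGVRS
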