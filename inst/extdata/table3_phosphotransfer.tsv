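donor	Bs0F	Dt0F	Bs0A	Dt0A	Ca0A
BsKinA	+	+	-	-	-
Bs0B	+	+	+	+	+
Dt1918	+	+	+	-	+
Dt0B	+	+	+	+	+
Ca0903	-	-	+	+	+
Ca3319	+	+	+	+	+
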