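kinase	Inhib01	Inhib02	Inhib03
KIN311	-	3.55647	0.363007
KIN143	NA	-	NA
KIN064	NA	-	7.65361
KIN218	0.0533341	NA	0.298781
KIN136	-	-	NA
KIN039	-	NA	-
KIN118	NA	NA	-
KIN293	6.7656	NA	-
KIN014	NA	-	0.021563
KIN346	NA	-	NA
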