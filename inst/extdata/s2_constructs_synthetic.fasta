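>BsKinA
GKPIDKGCCRFANRGTYNNWHMKMMRHKSALEELTSPLPVMNSQPTSSQSFAYTGKAMDDVHRILDCTPHMEAGDGFQTNLHWCECQSGMMKLFEVWAQNGFWHLAGDCKLSIVFHNRHRRYGKYITLPTWMISDQISWGVMTNIMDCEWNPSTKLERRMWLIGFLCCTS
>Bs0F
GKPIDKGCCRFANRGTYNNWHMKMMRHKSAMLKRDYLFQQFAVYTSMWDWNQCFKNWIFDWADVGSEDPKANFNGNIEHTDNQDQCDHIFGGQGIGATMNCRTSYNIKDWCIEKMNLETFISRTCAWWETVDRNVDDAYVMVIRQITAREDWTVNLLKQNQSEPH
>Bs0B
GKPIDKGCCRFANRGTYNNWHMKMMRHKSAAIHYGHFTVPWIAHSEVDTNHWDTKHIWDGCWCRFYFEAKSDLVDFGRFSFWCLSESMDDTVRMFICQTHMELGMGNSKNLPWCHDASQMDNLFKVWRNPGFAKLAGDCNLSIVCHVNHRRMGKYFTLPFINEWHGNYKQ
>Bs0A
GKPIDKGCCRFANRGTYNNWHMKMMRHKSAMLFYWRKQWQFYVYWIMWGWYQCFKWWEFDWCVLESEEENAAFNERIELGENNDQCDPIAGGQELGAEMKYRTSYNIKDWCIQKYNLETFASRTCWWWYTLVMFYDPCCVMEVRSGLSIIANDFWMDWMGKGDVK
>Dt1918
GKPIDKGCCRFANRGTYNNWHMKMMRHKSAKLMYGLVDIWCYYNILDCFYFAYLGESFDDEHQIFDCTNHMETGDGFQENLHWCPCRSYMFNLPHVWDNPGFWHLAGDCNFSIVFSVKHRRMGQYFAQLFAYQSHTPMMSLHNAIFCTINIPKSNMNYMRCETKRNDCNT
>Dt0F
GKPIDKGCCRFANRGTYNNWHMKMMRHKSALLKHAYQQWQFYSMWIMWGCNQCFKKWAFDQHGLESEEPNFAFPENIELGDNQDQCDTIFGGQGIGSEMECRTSYRCKRWCWQALNLEGFARRTCWWWYTLMMEVDWAYVMVVLSTHLSVPMGKKCIEFDVIPAM
>Dt0B
GKPIDKGCCRFANRGTYNNWHMKMMRHKSALIHYVHFTVFWHAHIENDRWAWDTYHIWDWCWCRFYFGAKSDWNCGGRFSFMYLGFSMGDNTAMFSCQTHIEVGDGLQKHLHWCNKRSQMMNLPEVMDNPGFWHLAGFCNLSTVFHVVHGRMGKYVTLSFFVHFGMNINF
>Dt0A
GKPIDKGCCRFANRGTYNNWHMKMMRHKSAMLKAWYKQWQKYVHTQMFGWNMCFQHWIFDWCGLVSEETNQLLNERIELGANNDQWDTIFAGQEFGEEMKCRTSYNIGDLCMQKLNLDCFARRTFWWWWTSVMEFDDAYVMIVFFVRDKPWMDRWTFWHTCCKVQ
>Ca0903
GKPIDKGCCRFANRGTYNNWHMKMMRHKSAKQYGAFCYDHMQWFKFSCRWFAKLGESMDDWHNMFDCNTHMEISKGAQKNLMWDECHSEMMGLHEVWDNMGWWHLAGDCNDSPVPHVVHRRMGKKFTLHFPWFHVNEMGQATTRRYSRGMAYFHRGRNWYCKYFEWGTPL
>Ca3319
GKPIDKGCCRFANRGTYNNWHMKMMRHKSAQNQECHQPKYRPRTCRKTDAFNGVGMSMDIEHRPFDCSTHMEVGDGLQRDLATCVCRSQMMNLTEVWDNPCQDEHEGDVNLSDHFHRNPRRMGFYFTEPFHMGDGFDLNVVHPEREIIMLQTRNSIYQQLPFKRKTKYQH
>Ca0A
GKPIDKGCCRFANRGTYNNWHMKMMRHKSAMLCRWYKQRSFYFWWIMWGWYQKFKFEIFDWHESEEEEPNADFNERIHLGDNNDCCDTIFGGSEFCGEMKSRMSYNRKDWCIQKLNIDMFCRRTCQWWYTLFCAYDFLYVMPVFSMYDVVCICHGGIMQCFQWYY
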