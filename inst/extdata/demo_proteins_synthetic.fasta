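>SYNP1 synthetic demo protein 1
CGQISIVFWRWYILSCRCRFKRQCTFPTKKSFRAQQKAKPWWPVCSVFQPKESLEIKRSF
KVHPGTWIGFPRPSGIFKQDRDLKQLAGRCMWPKERILANFQDMDTRKDTKPTKVWCRLD
YKTRIKNTYASKKSEQQKKNWHRSPAMDNHHSYRESRKLRKECRTTKPMHCIVTVPVKTN
RYFEDAEEIRKKRKRKLLWYAKQRCKMVKCPWVSWSFTRR
>SYNP2 synthetic demo protein 2
KMWLDCLAFLKRAFIYVRTYVKHVKRVTDTLRRLRVFFIKRKMIDNLRYARKRKISPRHA
INKMRHAATKECAIMHTICRRPLIAKWNDCKFPHHKDAPKAPLYLVYAHRFAMIKMWWAW
HNTYGVNHQMWMWENDETHIEKNQETDNHQEWCKHPDKQRFGRQIVCPWHIRWRQCAWKE
LWQADKNNCERVDSMTTVQKDAITFAKGEAQDEPIYFYCM
>SYNP3 synthetic demo protein 3
DSYDMWSSLRNESFQVVIITWFEHVGHPLKMKSDFDMIRCNECHYRWLRVAYFTNCRCMT
ASNFCKHSNCKKMCSRILRYVTHAIIDNKDICGNEKIGTMTMVQKPRRIPLMFWKMRESC
EMNPYKNRITGNDKMHCRATDKTVYIGLPPEKWCRYKIMPETFQHICFYTQISVEANHWI
PSKKKCREALGYLFLCCLDGRKNMPKDEAVSKRNECKQHE
>SYNP4 synthetic demo protein 4
MPFMWKGLWRKQYMKDLSQCDNKSPSLFEKYGRMQRRYWKGNTREKDGKFGCEVTKWDRI
VRIADRDEQQFRNCMKILDRARGLGTSVLQSNVKGLAKRENEVMNALSYSPKKKTSSMWA
LYERTHRPYKINGHSPKDVRARTDNMRSCRKFNLSLPLEGYLMDTFERERMNRFRDKLIN
KHYCSPGHTQHRYHKPTMYCAWYHCPRVCVCAKDRPFGLP
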