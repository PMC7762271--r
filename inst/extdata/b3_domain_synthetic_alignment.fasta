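>B3_syn01 synthetic B3-domain alignment member
VSDKRKVPIMPPAVIHHDAMNMTNQGSKEGMTSAYLYDAWGRLWYRGIGYKTYFKRKKLG
WDQFVLEGNLPGGDRSAFASTASHRVHTHF
>B3_syn02 synthetic B3-domain alignment member
VSDKRKCPIMPPAVIHHDPMNMMNQGSVEGMTSAYLYDAWGTLWYRGIGWGTYFWIKKRG
WDQFVLETNLPGGTRMLHASTASHNVHFHF
>B3_syn03 synthetic B3-domain alignment member
VSDKRKCHIMPPAVIHHDPMNMMNQGSKEGMTSAYLYDAWGTLWYRDIGYGTYFWIKKLG
WDPFVLEGNLPGGDRSAFAATASHNVHTHF
>B3_syn04 synthetic B3-domain alignment member
VSDKRKCPIMPPAVIHHDPQNMMNQGSKEGMTSAYLYDAWGRRWYRGIGYGTYFWIKKLG
WDQFVLEGNLPGGDDSAFASTASHNVHTHF
>B3_syn05 synthetic B3-domain alignment member
VSDTRKCPIMPPAVIHHDPMNMMNQGSKEGMTHAYLYDAWGRLWYRGIGYGTYFWIKKLI
WDQFYLCGNLPGGDRSAFASTASHNVHTHF
>B3_syn06 synthetic B3-domain alignment member
VSDKRKCPIMPPAVIYHDPMNMMNQGSKEGMTSAYLYDAWGRLWYRGIGYGTYFWKKKLG
WDCFVLEGNLPGGDRSAFASTASHNPHTHF
>B3_syn07 synthetic B3-domain alignment member
VSDIRKCPIMSPAVIHHDFMNMMNQGSKEGMTSAYLYDAWGRLWYRGIGYATYFWIKKNG
WCQFVLFGNLPGGDRSAFASTASHNVHTHF
>B3_syn08 synthetic B3-domain alignment member
QSDKRKCPIMPAQVIHADPMNMMNQGSKEGMTSAYLYDAWGRLWYRGIGYGTYFWIKKLG
WDQFVLEGNLMGSDRSAFAATASHNVHGHR
>B3_syn09 synthetic B3-domain alignment member
MSDKRRCPIMPPAVIHHDPMNMRNQGSKEGMTSAYLYDFNGRHWYSGIGAGTYFWPNKLG
WDQFVLEGQLMGGDRSYFASTASPNVHTHF
>B3_syn10 synthetic B3-domain alignment member
VSDKRKCPIMPPAVIHHDPMNMMNQGSKEGMTSAYLYDAWGSLWYRGIGMGTYFWIKKLG
WDQFVLEGNLPGGDRSAFSQTASHNVMTHF
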