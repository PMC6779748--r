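# Built-in mini-lexicon, LIWC-dic-like format: one category per line,
#   name: entry, entry, ...
# Entries are lowercase literals or prefix patterns ending in '*'.
# This is a small open word list shipped for reproducibility; a user-supplied
# full dictionary in the same format can be passed to load_lexicon().
first_person_singular: i, me, my, mine, myself, i'm, i've, i'll, i'd, im
first_person_plural: we, us, our, ours, ourselves, we're, we've, we'll, we'd, lets
second_person: you, your, yours, yourself, yourselves, you're, you've, you'll, you'd, u, ur, y'all
indefinite_pronoun: anybody, anyone, anything, everybody, everyone, everything, nobody, somebody, someone, something, whatever, whoever, other*, another, none
quantifier: all, alot, lot, lots, few, fewer, many, much, more, most, some, several, plenty, bunch, couple, ton, tons, every, each, both, half, single
negation: no, not, never, none, nothing, nowhere, cannot, can't, don't, won't, wouldn't, couldn't, shouldn't, didn't, doesn't, isn't, aren't, wasn't, ain't, neither, nor, without
verbs: am, is, are, was, were, be, been, being, have, has, had, do, does, did, go, goes, going, went, gone, get, gets, got, make, makes, made, take, takes, took, come, comes, came, see, sees, saw, know, knows, knew, think*, say, says, said, want*, need*, feel*, look*, give, gave, keep*, tell, told, run*, walk*, talk*
future_tense: will, gonna, gotta, shall, tomorrow, soon, someday, upcoming, later, tonight, next
causation: because, cause, cuz, effect*, hence, therefore, thus, since, reason*, result*, lead*, led, make*, force*, depend*
insight: think*, know*, realize*, understand*, believ*, feel, sense, wonder*, figur*, aware*, notice*, recogni*, reflect*, insight*, learn*
discrepancies: should, would, could, ought, wish*, hope*, want*, need*, lack*, instead, rather, prefer*, ideal*, if
tentativeness: maybe, perhaps, possibl*, probabl*, guess*, kind, kinda, sort, sorta, seem*, appear*, unsure, unclear, somewhat, might, may, almost
certainty: always, never, absolutely, definitely, certain*, sure*, clearly, obvious*, totally, completely, every, undoubtedly, must, truly, exact*
inclusive: and, with, include*, including, together, both, also, along, plus, add*, we're
exclusive: but, except, without, exclude*, however, although, though, either, or, versus, unless
family: family, families, mom, moms, mother*, dad, dads, father*, brother*, sister*, son, sons, daughter*, grandma*, grandpa*, grandmother*, grandfather*, aunt*, uncle*, cousin*, wife, husband*, parent*, sibling*, stepmom, stepdad
friends: friend*, buddy, buddies, pal, pals, bestie*, bff*, neighbor*, roommate*, mate, mates, companion*, crew, squad, homie*
humans: people, person, human*, man, men, woman, women, guy, guys, girl*, boy*, kid, kids, child*, adult*, baby, babies, folks, citizen*, stranger*
home: home, homes, house*, apartment*, kitchen*, bedroom*, bathroom*, yard*, garage*, roof*, door*, window*, furniture*, couch*, rent, landlord*, neighborhood*
work: work*, job, jobs, boss*, career*, office*, employ*, unemploy*, coworker*, colleague*, business*, salary*, wage*, shift, shifts, hire*, fired, interview*, resume*, meeting*, deadline*, project*, manager*
achievement: achiev*, accomplish*, succeed*, success*, win, wins, winner*, won, earn*, effort*, goal*, improve*, master*, award*, promot*, progress*, proud*, ambiti*, best, finish*, complete*
money: money, cash, dollar*, buck, bucks, pay*, paid, broke, bill, bills, debt*, loan*, price*, cost*, cheap*, expensive*, afford*, bank*, rich*, poor*, budget*, spend*, spent, save*
religion: god, gods, pray*, prayer*, church*, bible*, faith*, holy, heaven*, hell, bless*, spirit*, religio*, sacred*, lord, jesus, allah, worship*, sin, sins, soul*
death: death*, dead, die, died, dies, dying, kill*, suicid*, funeral*, grave*, coffin*, bury*, buried, fatal*, mourn*, corpse*, perish*
body: body, bodies, arm, arms, leg, legs, head, heads, face*, hand*, foot, feet, skin, hair*, eye, eyes, heart*, blood*, stomach*, brain*, bone*, muscle*, neck*, mouth*
health: health*, sick*, ill, illness*, doctor*, nurse*, hospital*, clinic*, medicat*, medicine*, pill*, therap*, symptom*, diagnos*, flu, fever*, pain*, ache*, injur*, heal*, recover*, prescription*
bio: eat*, ate, food*, hungry, sleep*, slept, tired*, awake, breath*, drink*, drank, exercise*, gym, run*, sweat*, sex*, nap*, digest*
sexual: sex*, sexy, sexual*, kiss*, naked*, horny, porn*, lust*, intimat*, aroused*, erotic*
feel: feel, feels, feeling*, felt, touch*, soft*, rough*, smooth*, warm*, cold*, numb*, hard, texture*, grab*, hold*, held
hear: hear*, heard, listen*, sound*, noise*, noisy, loud*, quiet*, voice*, voices, whisper*, music*, song*, ring*, echo*, silence*, silent*
anger: anger*, angry, angrier, mad, madder, hate*, hated, hating, rage*, furious*, annoy*, irritat*, frustrat*, pissed, resent*, hostil*, outrage*, fight*, fought, argue*, argument*, yell*, scream*
anxiety: anxi*, worry*, worried, worries, nervous*, afraid, scared, scare*, fear*, panic*, stress*, tense*, uneasy, dread*, overwhelm*, restless*, paranoi*
sadness: sad, sadder, sadness*, cry, crying, cried, cries, tear, tears, grief*, griev*, depress*, lonely, lonelier, loneliness, miserable*, hopeless*, gloom*, hurt*, heartbroken*, sorrow*, empty
negative_affect: bad, worse, worst, awful*, terrible*, horrible*, nasty, ugly, hate*, hurt*, sad, angry, afraid, annoy*, miserable*, wrong*, fail*, problem*, worthless*, disgust*, evil*, stupid*, pathetic*
inhibition: stop*, stopped, block*, constrain*, restrain*, restrict*, avoid*, prevent*, hold, held, control*, forbid*, prohibit*, hesitat*, ban, banned, limit*
swear: damn*, dammit, hell, crap*, shit*, fuck*, bitch*, bastard*, asshole*, piss*, screw*, sucks, sucked, wtf, bullshit*
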